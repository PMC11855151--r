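#' Simulation configuration
#'
#' Describes a synthetic study: a differential-expression screen with a
#' planted significant fraction, an interaction-prediction table with
#' planted hub lncRNAs and planted structurally equivalent blocks, a
#' gene-set collection with planted enriched sets, and a binary
#' alteration matrix with a planted co-altered pair. All generators are
#' pure functions of this configuration: the same seed gives
#' byte-identical outputs.
#'
#' Defaults sketch a mid-sized RNA-seq contrast: 5000 annotated
#' transcripts of which 30% carry lncRNA biotypes, 500 truly DE, planted
#' effects around 1.5 log2 units, five hub regulators an order of
#' magnitude above the background degree cap, three equivalence blocks
#' of four lncRNAs sharing 90% of their targets, 500 gene sets, and a
#' 5000-sample alteration panel with one gene pair co-altered at odds
#' ratio 16 over a 5% base alteration rate.
#'
#' @param n_transcripts Number of annotated transcripts.
#' @param lncrna_fraction Fraction of transcripts given lncRNA biotypes.
#' @param n_significant Number of planted truly-DE transcripts; must not
#'   exceed \code{n_transcripts}.
#' @param effect_log2fc_mean,effect_log2fc_sd Planted effect sizes, log2
#'   units; magnitudes are floored at log2(1.5) so every planted row
#'   clears the conventional fold threshold.
#' @param n_hub_lncrnas,hub_degree Planted hubs and their exact number of
#'   significant mRNA targets; \code{hub_degree} must exceed
#'   \code{background_degree_max}.
#' @param background_degree_max Cap on significant targets of non-hub
#'   lncRNAs.
#' @param n_equivalence_blocks,block_size,block_target_overlap Planted
#'   structurally equivalent blocks: groups of \code{block_size} lncRNAs
#'   sharing at least \code{block_target_overlap} of their target sets.
#' @param n_gene_sets Number of gene sets in the synthetic collection.
#' @param planted_enriched_set_overlap Hub-target genes planted into each
#'   enriched set.
#' @param n_samples Rows of the alteration matrix.
#' @param alteration_base_rate Per-gene marginal alteration probability.
#' @param planted_pair_odds_ratio Population odds ratio of the planted
#'   co-altered pair (> 0).
#' @param seed Integer RNG seed.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_transcripts = 5000L,
                       lncrna_fraction = 0.3,
                       n_significant = 500L,
                       effect_log2fc_mean = 1.5,
                       effect_log2fc_sd = 0.5,
                       n_hub_lncrnas = 5L,
                       hub_degree = 120L,
                       background_degree_max = 15L,
                       n_equivalence_blocks = 3L,
                       block_size = 4L,
                       block_target_overlap = 0.9,
                       n_gene_sets = 500L,
                       planted_enriched_set_overlap = 15L,
                       n_samples = 5000L,
                       alteration_base_rate = 0.05,
                       planted_pair_odds_ratio = 16,
                       seed = 1L) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    lncrna_fraction = lncrna_fraction,
    n_significant = as.integer(n_significant),
    effect_log2fc_mean = effect_log2fc_mean,
    effect_log2fc_sd = effect_log2fc_sd,
    n_hub_lncrnas = as.integer(n_hub_lncrnas),
    hub_degree = as.integer(hub_degree),
    background_degree_max = as.integer(background_degree_max),
    n_equivalence_blocks = as.integer(n_equivalence_blocks),
    block_size = as.integer(block_size),
    block_target_overlap = block_target_overlap,
    n_gene_sets = as.integer(n_gene_sets),
    planted_enriched_set_overlap = as.integer(planted_enriched_set_overlap),
    n_samples = as.integer(n_samples),
    alteration_base_rate = alteration_base_rate,
    planted_pair_odds_ratio = planted_pair_odds_ratio,
    seed = as.integer(seed)
  )
  counts <- c("n_transcripts", "n_significant", "n_hub_lncrnas",
              "hub_degree", "background_degree_max", "n_equivalence_blocks",
              "block_size", "n_gene_sets", "planted_enriched_set_overlap",
              "n_samples")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      stop("`", f, "` must be a non-negative count", call. = FALSE)
    }
  }
  for (f in c("lncrna_fraction", "block_target_overlap",
              "alteration_base_rate")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("`", f, "` must be a proportion in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$n_significant > cfg$n_transcripts) {
    stop("`n_significant` cannot exceed `n_transcripts`", call. = FALSE)
  }
  if (cfg$n_hub_lncrnas > 0L &&
      cfg$hub_degree <= cfg$background_degree_max) {
    stop("`hub_degree` must exceed `background_degree_max`", call. = FALSE)
  }
  if (cfg$planted_pair_odds_ratio <= 0) {
    stop("`planted_pair_odds_ratio` must be positive", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Run `expr` under a derived seed without disturbing the caller's RNG.
with_sim_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

# Small stable hash of a label so per-contrast draws differ by label.
label_offset <- function(label) {
  sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 10000L
}

#' Simulate a DESeq2-style differential-expression table
#'
#' Emits \code{n_transcripts} rows in the external dialect
#' (transcript_id, symbol, biotype, baseMean, log2FoldChange, pvalue,
#' padj). Planted rows draw their p-value from a heavily left-skewed
#' Beta(0.05, 1), truncated so that every planted row clears the BH
#' threshold at q <= 0.1, and their |log2FoldChange| from a normal
#' floored at log2(1.5); null rows draw p ~ Uniform(0, 1) and small null
#' fold changes. padj is BH over all p-values. Transcript identity
#' (ID, symbol, biotype) depends only on the seed, so multiple contrasts
#' generated from one config share a stable annotation, while the
#' statistics vary by \code{contrast_label}.
#'
#' @param config A [sim_config()].
#' @param contrast_label Label naming the contrast.
#' @return List with \code{table} (the DE data.frame) and \code{truth}
#'   (list: \code{significant_ids}, \code{significant_lncrna_ids},
#'   \code{significant_mrna_ids}).
#' @export
simulate_de_table <- function(config, contrast_label = "contrast1") {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_transcripts
  empty <- data.frame(transcript_id = character(0), symbol = character(0),
                      biotype = character(0), baseMean = numeric(0),
                      log2FoldChange = numeric(0), pvalue = numeric(0),
                      padj = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(table = empty,
                truth = list(significant_ids = character(0),
                             significant_lncrna_ids = character(0),
                             significant_mrna_ids = character(0))))
  }
  anno <- with_sim_seed(config$seed, {
    ids <- sprintf("ENSG%011d", seq_len(n))
    n_lnc <- round(n * config$lncrna_fraction)
    lnc_rows <- sort(sample.int(n, n_lnc))
    biotype <- rep(NA_character_, n)
    # composition loosely mirrors real lncRNA catalogues: antisense and
    # lincRNA dominate, minor classes trail
    biotype[lnc_rows] <- sample(
      c("antisense", "lincRNA", "sense_intronic", "sense_overlapping",
        "processed_transcript"),
      n_lnc, replace = TRUE, prob = c(0.48, 0.44, 0.04, 0.02, 0.02))
    biotype[-lnc_rows] <- sample(
      c("protein_coding", "processed_pseudogene", "unprocessed_pseudogene"),
      n - n_lnc, replace = TRUE, prob = c(0.90, 0.06, 0.04))
    symbol <- ifelse(seq_len(n) %in% lnc_rows,
                     sprintf("LNC%05d", seq_len(n)),
                     sprintf("GENE%05d", seq_len(n)))
    list(ids = ids, biotype = biotype, symbol = symbol)
  })
  stats_seed <- config$seed + 101L + label_offset(contrast_label)
  tab <- with_sim_seed(stats_seed, {
    sig <- sort(sample.int(n, config$n_significant))
    p <- stats::runif(n)
    log2fc <- stats::rnorm(n, 0, 0.2)
    if (config$n_significant > 0L) {
      # Beta(0.05, 1) truncated to [0, cap]: inverse-CDF draw cap * U^20.
      # cap is half the BH threshold at rank n_significant, so every
      # planted row is guaranteed q <= 0.05 <= 0.1 after adjustment.
      cap <- 0.05 * config$n_significant / n
      p[sig] <- cap * stats::runif(config$n_significant)^20
      # floored at 0.585 log2 units, strictly above log2(1.5), so planted
      # rows still clear an inclusive 1.5-fold threshold after the table
      # has round-tripped through finite-precision text
      mag <- pmax(0.585,
                  stats::rnorm(config$n_significant,
                               config$effect_log2fc_mean,
                               config$effect_log2fc_sd))
      log2fc[sig] <- mag * sample(c(-1, 1), config$n_significant,
                                  replace = TRUE)
    }
    data.frame(
      transcript_id = anno$ids, symbol = anno$symbol,
      biotype = anno$biotype,
      baseMean = stats::rlnorm(n, meanlog = 5, sdlog = 1.5),
      log2FoldChange = log2fc, pvalue = p,
      padj = stats::p.adjust(p, method = "BH"),
      stringsAsFactors = FALSE
    ) -> df
    attr(df, "sig_rows") <- sig
    df
  })
  sig_ids <- tab$transcript_id[attr(tab, "sig_rows")]
  sig_bio <- tab$biotype[attr(tab, "sig_rows")]
  attr(tab, "sig_rows") <- NULL
  list(table = tab,
       truth = list(
         significant_ids = sig_ids,
         significant_lncrna_ids = sig_ids[sig_bio %in% lncrna_biotypes()],
         significant_mrna_ids = sig_ids[sig_bio == "protein_coding"]
       ))
}

#' Simulate a lncRNA-mRNA interaction-prediction table
#'
#' Builds an edge table referencing the IDs of a simulated DE table.
#' Planted hubs receive exactly \code{hub_degree} significant-mRNA
#' targets; planted equivalence-block members share a core of at least
#' \code{block_target_overlap} of their target sets (block cores are
#' drawn disjointly across blocks, so cross-block similarity stays
#' near zero); remaining significant lncRNAs receive up to
#' \code{background_degree_max} significant targets. Noise edges from
#' and to non-significant transcripts are added so that intersecting
#' with the significant sets does real work, as it does on real data.
#'
#' @param config A [sim_config()].
#' @param de Result of [simulate_de_table()] (list with table + truth).
#' @return List with \code{table} (lncrna_id, mrna_id, mode) and
#'   \code{truth} (list: \code{hub_ids}, \code{equivalence_blocks} — a
#'   list of ID vectors — and \code{hub_targets}, a list mapping hub ID
#'   to its planted target IDs).
#' @export
simulate_interaction_table <- function(config, de) {
  stopifnot(inherits(config, "sim_config"))
  sig_lnc <- de$truth$significant_lncrna_ids
  sig_mrna <- de$truth$significant_mrna_ids
  n_planted_lnc <- config$n_hub_lncrnas +
    config$n_equivalence_blocks * config$block_size
  if (length(sig_lnc) < n_planted_lnc) {
    stop("not enough significant lncRNAs (", length(sig_lnc),
         ") for the planted hubs and blocks (", n_planted_lnc, ")",
         call. = FALSE)
  }
  if (config$hub_degree > length(sig_mrna)) {
    stop("`hub_degree` (", config$hub_degree, ") exceeds the number of ",
         "significant mRNAs (", length(sig_mrna), ")", call. = FALSE)
  }
  d_block <- config$background_degree_max
  core_size <- ceiling(config$block_target_overlap * d_block)
  if (config$n_equivalence_blocks > 0L) {
    if (d_block < 1L) {
      stop("equivalence blocks need `background_degree_max` >= 1",
           call. = FALSE)
    }
    if (config$n_equivalence_blocks * core_size > length(sig_mrna)) {
      stop("not enough significant mRNAs for disjoint block cores",
           call. = FALSE)
    }
  }
  all_ids <- de$table$transcript_id
  nonsig_lnc <- setdiff(
    all_ids[de$table$biotype %in% lncrna_biotypes()], sig_lnc)
  nonsig_mrna <- setdiff(
    all_ids[de$table$biotype == "protein_coding"], sig_mrna)
  res <- with_sim_seed(config$seed + 202L, {
    planted <- sample(sig_lnc, n_planted_lnc)
    hubs <- if (config$n_hub_lncrnas > 0L) {
      planted[seq_len(config$n_hub_lncrnas)]
    } else character(0)
    block_members <- planted[setdiff(seq_len(n_planted_lnc),
                                     seq_len(config$n_hub_lncrnas))]
    blocks <- if (config$n_equivalence_blocks > 0L) {
      split(block_members,
            rep(seq_len(config$n_equivalence_blocks),
                each = config$block_size))
    } else list()
    edges <- list()
    hub_targets <- list()
    for (h in hubs) {
      tg <- sample(sig_mrna, config$hub_degree)
      hub_targets[[h]] <- tg
      edges[[length(edges) + 1L]] <- data.frame(
        lncrna_id = h, mrna_id = tg, stringsAsFactors = FALSE)
    }
    core_pool <- sig_mrna
    for (b in blocks) {
      core <- sample(core_pool, core_size)
      core_pool <- setdiff(core_pool, core)
      for (m in b) {
        priv <- if (d_block > core_size) {
          sample(setdiff(sig_mrna, core), d_block - core_size)
        } else character(0)
        edges[[length(edges) + 1L]] <- data.frame(
          lncrna_id = m, mrna_id = c(core, priv), stringsAsFactors = FALSE)
      }
    }
    background <- setdiff(sig_lnc, planted)
    for (l in background) {
      k <- sample.int(config$background_degree_max + 1L, 1L) - 1L
      tg <- if (k > 0L) sample(sig_mrna, k) else character(0)
      # noise targets outside the significant set; removed on intersection
      noise <- if (length(nonsig_mrna)) {
        sample(nonsig_mrna, min(3L, length(nonsig_mrna)))
      } else character(0)
      if (length(tg) + length(noise)) {
        edges[[length(edges) + 1L]] <- data.frame(
          lncrna_id = l, mrna_id = c(tg, noise), stringsAsFactors = FALSE)
      }
    }
    if (length(nonsig_lnc)) {
      n_noise <- min(2L * length(sig_lnc), length(nonsig_lnc))
      noise_lnc <- sample(nonsig_lnc, n_noise)
      pool <- c(sig_mrna, nonsig_mrna)
      edges[[length(edges) + 1L]] <- data.frame(
        lncrna_id = noise_lnc,
        mrna_id = sample(pool, n_noise, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, edges)
    tab <- tab[!duplicated(tab[c("lncrna_id", "mrna_id")]), , drop = FALSE]
    tab$mode <- sample(c("decoy", "co-factor"), nrow(tab), replace = TRUE,
                       prob = c(0.6, 0.4))
    rownames(tab) <- NULL
    list(table = tab,
         truth = list(hub_ids = hubs,
                      equivalence_blocks = lapply(unname(blocks), sort),
                      hub_targets = hub_targets))
  })
  res
}

# Joint Bernoulli cell probability p11 for two margins r and odds ratio
# psi, solved from p11 (1 - 2r + p11) = psi (r - p11)^2 on the feasible
# interval [max(0, 2r - 1), r].
solve_joint_p11 <- function(r, psi) {
  if (r == 0) return(0)
  if (r == 1) return(1)
  if (psi == 1) return(r * r)
  f <- function(p11) p11 * (1 - 2 * r + p11) - psi * (r - p11)^2
  lo <- max(0, 2 * r - 1)
  p11 <- stats::uniroot(f, c(lo, r), tol = 1e-14)$root
  cells <- c(1 - 2 * r + p11, r - p11, r - p11, p11)
  if (any(cells < -1e-12) || any(cells > 1 + 1e-12)) {
    stop("no valid joint distribution for rate ", r, " and odds ratio ",
         psi, call. = FALSE)
  }
  p11
}

#' Simulate a binary sample-by-gene alteration matrix
#'
#' Twelve genes altered independently at \code{alteration_base_rate},
#' except the planted pair (the first two columns), whose per-sample
#' joint Bernoulli distribution is solved in closed form so that the
#' population odds ratio equals \code{planted_pair_odds_ratio} while
#' both margins stay at the base rate.
#'
#' @param config A [sim_config()].
#' @return List with \code{matrix} (integer samples x 12 genes, sample
#'   IDs as rownames) and \code{truth} (list with
#'   \code{co_altered_pairs}: one element with \code{genes} and
#'   \code{odds_ratio}).
#' @export
simulate_alteration_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 1L) stop("`n_samples` must be >= 1", call. = FALSE)
  n <- config$n_samples
  r <- config$alteration_base_rate
  psi <- config$planted_pair_odds_ratio
  genes <- sprintf("ALT%02d", 1:12)
  p11 <- solve_joint_p11(r, psi)
  probs <- c(`00` = 1 - 2 * r + p11, `10` = r - p11,
             `01` = r - p11, `11` = p11)
  m <- with_sim_seed(config$seed + 303L, {
    joint <- sample.int(4L, n, replace = TRUE, prob = probs)
    m <- matrix(0L, nrow = n, ncol = 12L,
                dimnames = list(sprintf("S%06d", seq_len(n)), genes))
    m[, 1L] <- as.integer(joint %in% c(2L, 4L))
    m[, 2L] <- as.integer(joint %in% c(3L, 4L))
    for (j in 3:12) m[, j] <- stats::rbinom(n, 1L, r)
    m
  })
  list(matrix = m,
       truth = list(co_altered_pairs = list(
         list(genes = genes[1:2], odds_ratio = psi))))
}

#' Simulate a gene-set collection with planted enriched sets
#'
#' Background sets draw members uniformly from the protein-coding genes
#' of the DE table; for each planted hub one enriched set additionally
#' contains \code{planted_enriched_set_overlap} of that hub's target
#' genes, so that an over-representation analysis of the hub's target
#' set ranks it first.
#'
#' @param config A [sim_config()].
#' @param de Result of [simulate_de_table()].
#' @param interactions Result of [simulate_interaction_table()].
#' @return List with \code{collection} (a \code{gene_set_collection})
#'   and \code{truth} (list: \code{enriched_set_names}, parallel to the
#'   hub IDs).
#' @export
make_gene_sets <- function(config, de, interactions) {
  stopifnot(inherits(config, "sim_config"))
  universe <- de$table$transcript_id[de$table$biotype == "protein_coding"]
  if (config$planted_enriched_set_overlap > config$hub_degree) {
    stop("`planted_enriched_set_overlap` cannot exceed `hub_degree`",
         call. = FALSE)
  }
  hubs <- interactions$truth$hub_ids
  n_bg <- config$n_gene_sets
  with_sim_seed(config$seed + 404L, {
    sets <- list()
    desc <- character(0)
    planted_names <- character(0)
    for (i in seq_along(hubs)) {
      nm <- sprintf("PLANTED_SET_%02d", i)
      overlap <- sample(interactions$truth$hub_targets[[hubs[i]]],
                        config$planted_enriched_set_overlap)
      filler <- sample(setdiff(universe, overlap),
                       max(0L, 50L - length(overlap)))
      sets[[nm]] <- c(overlap, filler)
      desc <- c(desc, sprintf("synthetic set enriched for hub %s targets",
                              hubs[i]))
      planted_names <- c(planted_names, nm)
    }
    for (i in seq_len(n_bg)) {
      nm <- sprintf("SET%04d", i)
      sets[[nm]] <- sample(universe, sample(20:150, 1L))
      desc <- c(desc, "synthetic background set")
    }
    list(collection = gene_set_collection(sets, descriptions = desc),
         truth = list(enriched_set_names = planted_names))
  })
}

#' TSV writers for simulated inputs
#'
#' Write the simulated DE table, interaction table and alteration matrix
#' in the dialects the readers of this package (and common external
#' tools) expect.
#'
#' @param table Data.frame (or matrix for the alteration writer).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @name sim_writers
NULL

#' @rdname sim_writers
#' @export
write_de_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname sim_writers
#' @export
write_interactions <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname sim_writers
#' @export
write_alteration_matrix <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate and write a full synthetic input bundle
#'
#' Runs every generator for one or more contrast labels and writes the
#' DE tables (\code{de_<label>.tsv}), the shared interaction table
#' (\code{interactions.tsv}), the gene-set collection
#' (\code{gene_sets.gmt}), the alteration matrix
#' (\code{alterations.tsv}) and the combined planted truth
#' (\code{truth.json}) into a directory.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @param contrast_labels Character vector of contrast labels.
#' @return Invisibly, a list with the file paths and the combined truth.
#' @export
synth_inputs <- function(config, dir,
                         contrast_labels = "contrast1") {
  stopifnot(inherits(config, "sim_config"), length(contrast_labels) >= 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  de_list <- lapply(contrast_labels, function(lb) {
    simulate_de_table(config, lb)
  })
  names(de_list) <- contrast_labels
  de_paths <- character(0)
  for (lb in contrast_labels) {
    p <- file.path(dir, paste0("de_", lb, ".tsv"))
    write_de_table(de_list[[lb]]$table, p)
    de_paths[lb] <- p
  }
  inter <- simulate_interaction_table(config, de_list[[1L]])
  inter_path <- file.path(dir, "interactions.tsv")
  write_interactions(inter$table, inter_path)
  gs <- make_gene_sets(config, de_list[[1L]], inter)
  gmt_path <- file.path(dir, "gene_sets.gmt")
  write_gmt(gs$collection, gmt_path)
  alt <- simulate_alteration_matrix(config)
  alt_path <- file.path(dir, "alterations.tsv")
  write_alteration_matrix(alt$matrix, alt_path)
  truth <- list(
    de = lapply(de_list, `[[`, "truth"),
    hub_ids = inter$truth$hub_ids,
    equivalence_blocks = inter$truth$equivalence_blocks,
    enriched_set_names = gs$truth$enriched_set_names,
    co_altered_pairs = alt$truth$co_altered_pairs
  )
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(de_paths = de_paths, interactions = inter_path,
                 gene_sets = gmt_path, alterations = alt_path,
                 truth_path = truth_path, truth = truth))
}
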