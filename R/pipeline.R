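#' Read and validate a pipeline configuration
#'
#' Configurations are plain lists (or YAML files with the same shape):
#' \preformatted{
#' contrasts:
#'   - label: AF_vs_EU
#'     de_table: path/to/de_AF_vs_EU.tsv
#'     q_max: 0.1            # relaxed designs may use e.g. 0.4
#'     linear_fc_min: 1.5
#' interactions: path/to/interactions.tsv
#' gene_sets:
#'   go_bp: path/to/sets.gmt       # one ORA + BH per named collection
#' alterations: path/to/alterations.tsv   # optional
#' band_table: path/to/bands.tsv          # optional (columns id, band)
#' similarity: {metric: jaccard, threshold: 0.5, linkage: average}
#' top_k: 11
#' universe_policy: collection   # or network_mrnas / significant_mrnas
#' seed: 1
#' }
#' All thresholds are configuration, never hard-coded: studies routinely
#' pair a strict primary contrast (q <= 0.1) with relaxed secondary
#' contrasts (q <= 0.4) at the same fold threshold.
#'
#' @param config A list as above, or the path of a YAML file.
#' @return The validated configuration list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$contrasts) || !length(config$contrasts)) {
    stop("config error [contrasts]: at least one contrast is required",
         call. = FALSE)
  }
  for (i in seq_along(config$contrasts)) {
    ct <- config$contrasts[[i]]
    if (is.null(ct$label)) {
      stop("config error [contrasts]: contrast ", i, " has no label",
           call. = FALSE)
    }
    if (is.null(ct$de_table)) {
      stop("config error [contrasts]: contrast '", ct$label,
           "' has no de_table path", call. = FALSE)
    }
    config$contrasts[[i]]$q_max <- ct$q_max %||% 0.1
    config$contrasts[[i]]$linear_fc_min <- ct$linear_fc_min %||% 1.5
    filter_spec(config$contrasts[[i]]$q_max,
                config$contrasts[[i]]$linear_fc_min)  # validates
  }
  if (is.null(config$interactions)) {
    stop("config error [interactions]: interaction table path is required",
         call. = FALSE)
  }
  sim <- config$similarity %||% list()
  config$similarity <- list(metric = sim$metric %||% "jaccard",
                            threshold = sim$threshold %||% 0.5,
                            linkage = sim$linkage %||% "average")
  config$top_k <- as.integer(config$top_k %||% 11L)
  config$universe_policy <- config$universe_policy %||% "collection"
  if (!config$universe_policy %in%
      c("collection", "network_mrnas", "significant_mrnas")) {
    stop("config error [universe_policy]: must be one of collection, ",
         "network_mrnas, significant_mrnas", call. = FALSE)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  for (field in c("interactions", "alterations", "band_table")) {
    p <- config[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config error [", field, "]: file not found: ", p,
           call. = FALSE)
    }
  }
  for (ct in config$contrasts) {
    if (!file.exists(ct$de_table)) {
      stop("config error [contrasts]: DE table not found for '",
           ct$label, "': ", ct$de_table, call. = FALSE)
    }
  }
  gs <- config$gene_sets
  if (!is.null(gs)) {
    if (is.null(names(gs)) || any(names(gs) == "")) {
      names(gs) <- paste0("collection", seq_along(gs))
    }
    for (p in gs) {
      if (!file.exists(p)) {
        stop("config error [gene_sets]: GMT file not found: ", p,
             call. = FALSE)
      }
    }
    config$gene_sets <- gs
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", stage, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' For each configured contrast: parse and filter the DE table, classify
#' biotypes, intersect with the interaction predictions into a bipartite
#' regulatory network, rank lncRNAs by degree, compute target-set
#' similarity, cluster, extract structurally equivalent groups, and run
#' ORA of the network's target mRNAs against every gene-set collection.
#' When an alteration matrix is configured, all-pairs co-occurrence
#' statistics are added; with two or more contrasts the cross-contrast
#' lncRNA overlap partition is computed. Every stage writes its table
#' under \code{out_dir} and the run report — the chain of counts from
#' input transcripts down to equivalence groups, mirroring how such
#' analyses are narrated — is written as \code{report.json}.
#'
#' @param config List or YAML path accepted by [pipeline_config()].
#' @param out_dir Output directory.
#' @return The run report, invisibly (it is also written to
#'   \code{out_dir/report.json}).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  collections <- if (!is.null(config$gene_sets)) {
    run_stage("gene_sets", lapply(config$gene_sets, read_gmt))
  }
  band_table <- if (!is.null(config$band_table)) {
    run_stage("band_table", utils::read.delim(config$band_table,
                                              stringsAsFactors = FALSE))
  }
  interactions <- run_stage("interactions",
                            read_interactions(config$interactions))
  # hash over the analysis-relevant configuration with paths reduced to
  # basenames, so runs from different working directories compare equal
  hash_cfg <- config
  for (f in c("interactions", "alterations", "band_table")) {
    if (!is.null(hash_cfg[[f]])) hash_cfg[[f]] <- basename(hash_cfg[[f]])
  }
  if (!is.null(hash_cfg$gene_sets)) {
    hash_cfg$gene_sets[] <- basename(unlist(hash_cfg$gene_sets))
  }
  for (i in seq_along(hash_cfg$contrasts)) {
    hash_cfg$contrasts[[i]]$de_table <-
      basename(hash_cfg$contrasts[[i]]$de_table)
  }
  report <- list(
    tool = "lncnet",
    version = as.character(utils::packageVersion("lncnet")),
    seed = config$seed,
    config_hash = rlang::hash(hash_cfg),
    contrasts = list()
  )
  sig_lnc_sets <- list()
  for (ct in config$contrasts) {
    lb <- ct$label
    cdir <- file.path(out_dir, lb)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    records <- run_stage("de_io_filter", read_de_table(ct$de_table))
    spec <- filter_spec(ct$q_max, ct$linear_fc_min)
    sig <- run_stage("de_io_filter", filter_significant(records, spec))
    contrast <- run_stage("de_io_filter", classify_biotypes(sig, lb))
    utils::write.table(sig, file.path(cdir, "significant.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    net <- run_stage("regulatory_network",
                     build_network(contrast, interactions))
    export_edges(net, file.path(cdir, "network.sif"), "sif")
    export_edges(net, file.path(cdir, "network.tsv"), "tsv")
    ranked <- run_stage("regulatory_network", suppressWarnings(
      rank_by_centrality(net, config$top_k)))
    if (!is.null(band_table) && nrow(ranked)) {
      ranked <- run_stage("regulatory_network",
                          annotate_locations(ranked, band_table))
    }
    utils::write.table(ranked, file.path(cdir, "ranked_lncrnas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ts <- target_sets(net)
    equiv <- NULL
    if (length(ts) >= 2L) {
      sim <- run_stage("structural_equivalence",
                       similarity_matrix(ts, config$similarity$metric))
      write_similarity(sim, file.path(cdir, "similarity.tsv"),
                       file.path(cdir, "similarity_long.tsv"))
      hc <- run_stage("structural_equivalence",
                      cluster_lncrnas(sim, config$similarity$linkage))
      if (!is.null(hc)) {
        dendrogram_newick(hc, file.path(cdir, "dendrogram.nwk"))
      }
      groups <- run_stage("structural_equivalence",
                          extract_groups(sim, ts,
                                         config$similarity$threshold))
      jsonlite::write_json(groups, file.path(cdir, "equivalence_groups.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      top_pair <- if (sum(ranked$top) >= 2L) {
        most_similar_pair(sim, ranked$lncrna_id[ranked$top])
      }
      equiv <- list(groups = groups, top_pair = top_pair)
    }
    enrich <- list()
    if (!is.null(collections) && nrow(net$edges)) {
      query <- net$mrna_nodes$id
      for (nm in names(collections)) {
        coll <- collections[[nm]]
        coll <- switch(config$universe_policy,
          collection = coll,
          network_mrnas = gene_set_collection(
            coll$sets, coll$descriptions, universe = net$mrna_nodes$id),
          significant_mrnas = gene_set_collection(
            coll$sets, coll$descriptions,
            universe = contrast$mrnas$transcript_id))
        res <- run_stage("enrichment_overlay",
                         suppressMessages(ora(query, coll)))
        write_ora(res, file.path(cdir, paste0("ora_", nm, ".tsv")))
        enrich[[nm]] <- utils::head(res, 10L)
      }
    }
    report$contrasts[[lb]] <- list(
      label = lb,
      filter = list(q_max = ct$q_max, linear_fc_min = ct$linear_fc_min),
      n_input_transcripts = nrow(records),
      n_testable = sum(records$testable),
      n_significant = nrow(sig),
      n_significant_lncrnas = nrow(contrast$lncrnas),
      n_significant_mrnas = nrow(contrast$mrnas),
      n_significant_other = nrow(contrast$other),
      biotype_composition = as.list(contrast$composition),
      n_network_lncrnas = nrow(net$lncrna_nodes),
      n_network_mrnas = nrow(net$mrna_nodes),
      n_edges = nrow(net$edges),
      n_distinct_target_mrnas = nrow(net$mrna_nodes),
      top_ranked = utils::head(
        ranked[c("lncrna_id", "symbol", "degree", "rank",
                 "direction", "chromosome_band")], config$top_k),
      most_similar_top_pair = equiv$top_pair,
      n_equivalence_groups = length(equiv$groups),
      n_structurally_equivalent_lncrnas =
        length(unlist(lapply(equiv$groups, `[[`, "member_ids"))),
      equivalence_group_sizes = vapply(
        equiv$groups %||% list(),
        function(g) length(g$member_ids), integer(1)),
      top_enriched_sets = enrich
    )
    sig_lnc_sets[[lb]] <- contrast$lncrnas$transcript_id
  }
  if (length(sig_lnc_sets) >= 2L) {
    ov <- run_stage("de_io_filter", overlap_contrasts(sig_lnc_sets))
    jsonlite::write_json(ov, file.path(out_dir, "lncrna_overlap.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$lncrna_overlap_counts <- as.list(ov$counts)
    report$lncrna_overlap_union <- ov$union_size
  }
  if (!is.null(config$alterations)) {
    m <- run_stage("cooccurrence",
                   read_alteration_matrix(config$alterations))
    co <- run_stage("cooccurrence", all_pairs(m))
    write_cooccurrence(co, file.path(out_dir, "cooccurrence.tsv"))
    report$cooccurrence <- utils::head(
      co[c("gene_a", "gene_b", "neither", "a_not_b", "b_not_a", "both",
           "log2_display", "p", "q", "tendency")], 10L)
    report$n_cooccurrence_pairs <- nrow(co)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the pipeline end-to-end on synthetic inputs
#'
#' Generates a full synthetic bundle with [synth_inputs()], builds the
#' matching configuration and runs [run_pipeline()]. Handy for smoke
#' tests and for exploring the report format.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory; inputs are written to
#'   \code{out_dir/inputs}.
#' @param contrast_labels Contrast labels to simulate.
#' @param q_max,linear_fc_min Filter thresholds applied to every
#'   simulated contrast.
#' @return List with \code{report} and \code{truth}.
#' @export
run_synthetic_pipeline <- function(config = sim_config(), out_dir,
                                   contrast_labels = "contrast1",
                                   q_max = 0.1, linear_fc_min = 1.5) {
  bundle <- synth_inputs(config, file.path(out_dir, "inputs"),
                         contrast_labels)
  pcfg <- list(
    contrasts = lapply(contrast_labels, function(lb) {
      list(label = lb, de_table = unname(bundle$de_paths[lb]),
           q_max = q_max, linear_fc_min = linear_fc_min)
    }),
    interactions = bundle$interactions,
    gene_sets = list(synthetic = bundle$gene_sets),
    alterations = bundle$alterations,
    seed = config$seed
  )
  report <- run_pipeline(pcfg, out_dir)
  list(report = report, truth = bundle$truth)
}
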