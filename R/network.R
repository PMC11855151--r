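#' Read a lncRNA-mRNA interaction prediction table
#'
#' Tab-separated with header columns \code{lncrna_id}, \code{mrna_id} and
#' an optional \code{mode} (e.g. decoy, co-factor). Duplicate
#' (lncrna_id, mrna_id) rows are collapsed on load — degree centrality
#' counts distinct targets, not prediction rows — keeping the first row's
#' mode.
#'
#' @param path Path to the TSV file.
#' @return Data.frame with columns \code{lncrna_id}, \code{mrna_id},
#'   \code{mode} (NA when absent from the file).
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("lncrna_id", "mrna_id"), names(df))
  if (length(missing)) {
    stop("interaction table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    lncrna_id = as.character(df$lncrna_id),
    mrna_id   = as.character(df$mrna_id),
    mode      = if ("mode" %in% names(df)) as.character(df$mode)
                else NA_character_,
    stringsAsFactors = FALSE
  )
  out[!duplicated(out[c("lncrna_id", "mrna_id")]), , drop = FALSE]
}

#' Build the bipartite regulatory network for one contrast
#'
#' Intersects an interaction-prediction table with the significant
#' transcripts of a contrast: an edge survives iff its lncRNA is a
#' significant lncRNA and its mRNA a significant (protein-coding) mRNA.
#' Significant lncRNAs with no surviving edge are dropped — in real data
#' this discards the large majority of DE lncRNAs, because most lack any
#' significantly DE predicted target. Node direction (up/down) is copied
#' from the DE sign.
#'
#' @param contrast A \code{contrast_result} from [classify_biotypes()]
#'   applied to a filtered table.
#' @param interactions Data.frame from [read_interactions()] (or the same
#'   shape).
#' @return Object of class \code{regulatory_network}: list with
#'   \code{edges} (lncrna_id, mrna_id, mode), \code{lncrna_nodes} and
#'   \code{mrna_nodes} (id, symbol, direction), restricted to nodes with
#'   at least one edge.
#' @export
build_network <- function(contrast, interactions) {
  stopifnot(inherits(contrast, "contrast_result"))
  if (!"mode" %in% names(interactions)) interactions$mode <- NA_character_
  interactions <- interactions[
    !duplicated(interactions[c("lncrna_id", "mrna_id")]), , drop = FALSE]
  lnc <- contrast$lncrnas
  mrna <- contrast$mrnas
  keep <- interactions$lncrna_id %in% lnc$transcript_id &
    interactions$mrna_id %in% mrna$transcript_id
  edges <- interactions[keep, c("lncrna_id", "mrna_id", "mode"), drop = FALSE]
  rownames(edges) <- NULL
  node_tbl <- function(de, ids) {
    i <- match(ids, de$transcript_id)
    data.frame(id = ids,
               symbol = de$symbol[i],
               direction = ifelse(de$log2fc[i] >= 0, "up", "down"),
               stringsAsFactors = FALSE)
  }
  structure(list(
    label = contrast$label,
    edges = edges,
    lncrna_nodes = node_tbl(lnc, sort(unique(edges$lncrna_id))),
    mrna_nodes = node_tbl(mrna, sort(unique(edges$mrna_id)))
  ), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %s: %d lncRNAs, %d mRNAs, %d edges\n",
              x$label, nrow(x$lncrna_nodes), nrow(x$mrna_nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Per-lncRNA target sets
#'
#' @param network A \code{regulatory_network}.
#' @return Named list mapping each lncRNA ID to the character vector of
#'   its distinct mRNA target IDs. The union of the values is the set of
#'   distinct network mRNAs.
#' @export
target_sets <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  if (!nrow(network$edges)) return(stats::setNames(list(), character(0)))
  lapply(split(network$edges$mrna_id, network$edges$lncrna_id), unique)
}

#' Rank lncRNAs by degree centrality
#'
#' Degree is the number of distinct mRNA targets a lncRNA is connected
#' to. All lncRNAs are returned sorted by non-increasing degree, ties
#' broken lexicographically by ID (the field convention when sources give
#' no rule), with the top \code{top_k} flagged.
#'
#' @param network A \code{regulatory_network}.
#' @param top_k How many leading ranks to flag; default 11, a typical
#'   size for a "hub" shortlist. If larger than the number of lncRNAs,
#'   all are flagged with a warning.
#' @return Data.frame with columns \code{lncrna_id}, \code{symbol},
#'   \code{degree}, \code{rank}, \code{direction}, \code{top},
#'   \code{chromosome_band} (empty until [annotate_locations()]).
#' @export
rank_by_centrality <- function(network, top_k = 11L) {
  stopifnot(inherits(network, "regulatory_network"))
  ts <- target_sets(network)
  ids <- names(ts)
  deg <- vapply(ts, length, integer(1))
  ord <- order(-deg, ids)
  out <- data.frame(
    lncrna_id = ids[ord],
    symbol = network$lncrna_nodes$symbol[
      match(ids[ord], network$lncrna_nodes$id)],
    degree = as.integer(deg[ord]),
    rank = seq_along(ord),
    direction = network$lncrna_nodes$direction[
      match(ids[ord], network$lncrna_nodes$id)],
    stringsAsFactors = FALSE
  )
  if (top_k > nrow(out)) {
    warning("top_k (", top_k, ") exceeds the number of lncRNAs (",
            nrow(out), "); flagging all", call. = FALSE)
    top_k <- nrow(out)
  }
  out$top <- out$rank <= top_k
  out$chromosome_band <- ""
  rownames(out) <- NULL
  out
}

#' Annotate a ranked lncRNA table with cytogenetic bands
#'
#' Left-joins a band table onto the ranking by ID, falling back to the
#' gene symbol for rows whose ID has no entry. Missing entries stay
#' empty; duplicated keys keep the first occurrence with a warning.
#'
#' @param ranked Output of [rank_by_centrality()].
#' @param band_table Data.frame with columns \code{id} and \code{band}
#'   (cytogenetic band, e.g. "Xq13.2"); \code{id} may hold transcript IDs
#'   or symbols.
#' @return \code{ranked} with \code{chromosome_band} filled where known.
#' @export
annotate_locations <- function(ranked, band_table) {
  if (!nrow(band_table)) return(ranked)
  stopifnot(all(c("id", "band") %in% names(band_table)))
  if (anyDuplicated(band_table$id)) {
    warning("band table has duplicated IDs; keeping first occurrence",
            call. = FALSE)
    band_table <- band_table[!duplicated(band_table$id), , drop = FALSE]
  }
  hit <- match(ranked$lncrna_id, band_table$id)
  fallback <- match(ranked$symbol, band_table$id)
  hit[is.na(hit)] <- fallback[is.na(hit)]
  band <- ifelse(is.na(hit), "", band_table$band[hit])
  n_miss <- sum(band == "")
  if (n_miss) {
    message("annotate_locations: ", n_miss,
            " lncRNA(s) without a band annotation")
  }
  ranked$chromosome_band <- band
  ranked
}

#' Export network edges for external visualisation
#'
#' \code{format = "sif"} writes Cytoscape simple-interaction-format lines
#' \code{source<TAB>interaction<TAB>target}, using the edge mode when
#' present and "regulates" otherwise. \code{format = "tsv"} writes a
#' self-contained table (lncrna_id, mrna_id, mode, lncrna_direction,
#' mrna_direction, plus symbols) from which [import_network_tsv()]
#' reconstructs the network.
#'
#' @param network A \code{regulatory_network}.
#' @param path Output file path.
#' @param format "sif" or "tsv".
#' @return \code{path}, invisibly.
#' @export
export_edges <- function(network, path, format = c("sif", "tsv")) {
  stopifnot(inherits(network, "regulatory_network"))
  format <- match.arg(format)
  e <- network$edges
  if (format == "sif") {
    interaction <- ifelse(is.na(e$mode) | e$mode == "", "regulates", e$mode)
    writeLines(paste(e$lncrna_id, interaction, e$mrna_id, sep = "\t"), path)
  } else {
    li <- match(e$lncrna_id, network$lncrna_nodes$id)
    mi <- match(e$mrna_id, network$mrna_nodes$id)
    out <- data.frame(
      lncrna_id = e$lncrna_id,
      mrna_id = e$mrna_id,
      mode = e$mode,
      lncrna_symbol = network$lncrna_nodes$symbol[li],
      mrna_symbol = network$mrna_nodes$symbol[mi],
      lncrna_direction = network$lncrna_nodes$direction[li],
      mrna_direction = network$mrna_nodes$direction[mi],
      stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Rebuild a regulatory network from its TSV export
#'
#' @param path File written by [export_edges()] with \code{format="tsv"}.
#' @param label Contrast label for the rebuilt network.
#' @return A \code{regulatory_network}.
#' @export
import_network_tsv <- function(path, label = "imported") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("lncrna_id", "mrna_id", "mode", "lncrna_symbol", "mrna_symbol",
            "lncrna_direction", "mrna_direction")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("network TSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  node_tbl <- function(ids, symbols, directions) {
    u <- sort(unique(ids))
    i <- match(u, ids)
    data.frame(id = u, symbol = symbols[i], direction = directions[i],
               stringsAsFactors = FALSE)
  }
  df$mode <- as.character(df$mode)
  structure(list(
    label = label,
    edges = data.frame(lncrna_id = df$lncrna_id, mrna_id = df$mrna_id,
                       mode = df$mode, stringsAsFactors = FALSE),
    lncrna_nodes = node_tbl(df$lncrna_id, df$lncrna_symbol,
                            df$lncrna_direction),
    mrna_nodes = node_tbl(df$mrna_id, df$mrna_symbol, df$mrna_direction)
  ), class = "regulatory_network")
}
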