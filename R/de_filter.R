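#' Significance filter specification
#'
#' Bundles the two thresholds applied to a differential-expression table:
#' a ceiling on the BH-adjusted p-value (q) and a floor on the linear fold
#' change. The linear threshold is applied to the magnitude of the signed
#' log2 fold change as \code{|log2fc| >= log2(linear_fc_min)}, so a
#' transcript halved in expression (log2fc = -1, linear FC magnitude 2)
#' passes a 1.5-fold threshold. Both comparisons are inclusive.
#'
#' @param q_max Maximum BH-adjusted p-value, in \[0, 1\].
#' @param linear_fc_min Minimum linear fold-change magnitude, >= 1.
#'   The default 1.5 is the conventional threshold for calling a
#'   transcript differentially expressed alongside q <= 0.1; relaxed
#'   designs (e.g. small supplementation trials) typically keep the fold
#'   threshold and raise \code{q_max}.
#' @return An object of class \code{filter_spec}.
#' @examples
#' filter_spec(0.1, 1.5)   # primary-contrast defaults
#' filter_spec(0.4, 1.5)   # relaxed q for low-powered contrasts
#' @export
filter_spec <- function(q_max = 0.1, linear_fc_min = 1.5) {
  stopifnot(is.numeric(q_max), length(q_max) == 1L, q_max >= 0, q_max <= 1)
  if (!is.numeric(linear_fc_min) || length(linear_fc_min) != 1L ||
      linear_fc_min < 1) {
    stop("`linear_fc_min` must be a single number >= 1", call. = FALSE)
  }
  structure(list(q_max = q_max, linear_fc_min = linear_fc_min),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> q <= %g and linear |FC| >= %g\n",
              x$q_max, x$linear_fc_min))
  invisible(x)
}

de_required_cols <- c("transcript_id", "symbol", "biotype",
                      "log2FoldChange", "pvalue", "padj")

#' Read a DESeq2-style differential-expression results table
#'
#' Expects a tab-separated file with a header containing at least
#' \code{transcript_id}, \code{symbol}, \code{biotype},
#' \code{log2FoldChange}, \code{pvalue} and \code{padj} (a \code{baseMean}
#' column is carried through when present). Rows with missing
#' \code{pvalue} or \code{padj} — as produced by DESeq2's independent
#' filtering — are retained but flagged \code{testable = FALSE} and can
#' never pass a significance filter.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of records with columns \code{transcript_id},
#'   \code{symbol}, \code{biotype}, \code{log2fc}, \code{p}, \code{q},
#'   \code{testable} (plus \code{baseMean} if present).
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(de_required_cols, names(df))
  if (length(missing)) {
    stop("DE table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    transcript_id = as.character(df$transcript_id),
    symbol        = as.character(df$symbol),
    biotype       = as.character(df$biotype),
    log2fc        = as.numeric(df$log2FoldChange),
    p             = as.numeric(df$pvalue),
    q             = as.numeric(df$padj),
    stringsAsFactors = FALSE
  )
  if ("baseMean" %in% names(df)) out$baseMean <- as.numeric(df$baseMean)
  if (anyDuplicated(out$transcript_id)) {
    stop("DE table ", path, " has duplicated transcript_id values",
         call. = FALSE)
  }
  out$testable <- !is.na(out$p) & !is.na(out$q)
  out
}

#' Filter a DE table at a significance threshold
#'
#' Returns the records with \code{q <= q_max} and
#' \code{|log2fc| >= log2(linear_fc_min)} (both inclusive). Records
#' flagged non-testable (missing p or q) are never returned. The signed
#' log2 fold change is preserved, so direction can be read off the result.
#'
#' @param records Data.frame from [read_de_table()] (or the same shape).
#' @param spec A [filter_spec()].
#' @return The significant subset of \code{records}, with an added
#'   \code{direction} column ("up" or "down").
#' @export
filter_significant <- function(records, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!"testable" %in% names(records)) {
    records$testable <- !is.na(records$p) & !is.na(records$q)
  }
  keep <- records$testable &
    records$q <= spec$q_max &
    abs(records$log2fc) >= log2(spec$linear_fc_min)
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc >= 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' ENSEMBL biotypes treated as lncRNA
#'
#' The default long-non-coding classes used when partitioning a filtered
#' table: antisense and lincRNA dominate real catalogues, with the minor
#' sense_intronic / sense_overlapping / processed_transcript and related
#' classes included per ENSEMBL convention.
#'
#' @return Character vector of biotype names.
#' @export
lncrna_biotypes <- function() {
  c("antisense", "lincRNA", "sense_intronic", "sense_overlapping",
    "processed_transcript", "3prime_overlapping_ncRNA",
    "bidirectional_promoter_lncRNA", "macro_lncRNA", "lncRNA")
}

#' Partition significant transcripts by biotype class
#'
#' Splits a set of (typically already filtered) DE records into lncRNA,
#' mRNA (protein_coding) and other buckets, and computes the biotype
#' composition of the lncRNA bucket (proportions over lncRNAs only).
#'
#' @param records Data.frame of DE records, usually the output of
#'   [filter_significant()].
#' @param label Contrast label carried through to reports.
#' @param lncrna_list Character vector of biotypes classed as lncRNA;
#'   defaults to [lncrna_biotypes()]. A plain-text file with one biotype
#'   per line can be loaded with \code{readLines()} and passed here.
#' @return An object of class \code{contrast_result} with elements
#'   \code{label}, \code{significant}, \code{lncrnas}, \code{mrnas},
#'   \code{other} (data.frames) and \code{composition} (named proportions
#'   over lncRNA biotypes, summing to 1 when any lncRNA is present).
#' @export
classify_biotypes <- function(records, label = "contrast",
                              lncrna_list = lncrna_biotypes()) {
  is_lnc <- records$biotype %in% lncrna_list
  is_mrna <- records$biotype == "protein_coding" & !is_lnc
  other <- records[!is_lnc & !is_mrna, , drop = FALSE]
  known <- c(lncrna_list, "protein_coding", "processed_pseudogene",
             "unprocessed_pseudogene", "transcribed_unprocessed_pseudogene",
             "miRNA", "snRNA", "snoRNA", "misc_RNA", "rRNA", "TEC")
  unknown <- setdiff(unique(other$biotype), known)
  if (length(unknown)) {
    message("classify_biotypes: ", length(unknown),
            " biotype(s) not in the lncRNA/protein_coding lists bucketed",
            " as 'other': ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  lnc <- records[is_lnc, , drop = FALSE]
  composition <- if (nrow(lnc)) {
    tab <- table(lnc$biotype)
    stats::setNames(as.numeric(tab) / nrow(lnc), names(tab))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(list(
    label = label,
    significant = records,
    lncrnas = lnc,
    mrnas = records[is_mrna, , drop = FALSE],
    other = other,
    composition = composition
  ), class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "<contrast_result> %s: %d significant (%d lncRNA, %d mRNA, %d other)\n",
    x$label, nrow(x$significant), nrow(x$lncrnas), nrow(x$mrnas),
    nrow(x$other)))
  invisible(x)
}

#' Cross-contrast overlap (Venn partition)
#'
#' Computes the full inclusion–exclusion partition of two or more ID sets:
#' one region per non-empty combination of membership, with the exact IDs
#' and count in each region. Region counts sum to the size of the union.
#'
#' @param id_sets Named list (length >= 2) of character vectors of IDs,
#'   e.g. significant lncRNA IDs per contrast.
#' @return A list with \code{regions} (named list mapping a region label
#'   like \code{"A&B"} to its ID vector), \code{counts} (named integer
#'   vector over the same regions) and \code{union_size}.
#' @export
overlap_contrasts <- function(id_sets) {
  if (!is.list(id_sets) || length(id_sets) < 2L) {
    stop("`id_sets` must be a named list of at least two ID vectors",
         call. = FALSE)
  }
  if (is.null(names(id_sets)) || any(names(id_sets) == "")) {
    names(id_sets) <- paste0("set", seq_along(id_sets))
  }
  id_sets <- lapply(id_sets, function(x) unique(as.character(x)))
  universe <- unique(unlist(id_sets, use.names = FALSE))
  membership <- vapply(id_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  key <- apply(membership, 1L, function(row) {
    paste(names(id_sets)[row], collapse = "&")
  })
  regions <- split(universe, key)
  # order regions by decreasing membership multiplicity, then label
  ord <- order(-vapply(strsplit(names(regions), "&", fixed = TRUE),
                       length, integer(1)), names(regions))
  regions <- regions[ord]
  list(regions = regions,
       counts = vapply(regions, length, integer(1)),
       union_size = length(universe))
}
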