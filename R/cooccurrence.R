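#' Read a binary sample-by-gene alteration matrix
#'
#' Tab-separated, first column \code{sample_id}, remaining columns one
#' per gene with entries in {0, 1} (1 = sample carries an alteration in
#' that gene, whatever the upstream calling combined: mutation, CNA,
#' expression).
#'
#' @param path TSV file path.
#' @return Integer matrix with sample IDs as rownames and genes as
#'   colnames.
#' @export
read_alteration_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "sample_id") {
    stop("alteration matrix ", path, " must have 'sample_id' as its first",
         " column", call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(!m %in% c(0L, 1L))) {
    stop("alteration matrix entries must be binary 0/1", call. = FALSE)
  }
  rownames(m) <- df$sample_id
  m
}

#' 2x2 contingency counts for one gene pair
#'
#' Counts samples by joint alteration status of two genes. The four
#' counts (neither, A-not-B, B-not-A, both) sum to the number of samples.
#'
#' @param matrix Binary matrix from [read_alteration_matrix()] (samples
#'   in rows, genes in columns).
#' @param gene_a,gene_b Column names.
#' @return Named integer vector \code{c(neither, a_not_b, b_not_a, both)}.
#' @export
contingency <- function(matrix, gene_a, gene_b) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% colnames(matrix)) {
      stop("gene ", g, " not present in the alteration matrix",
           call. = FALSE)
    }
  }
  a <- matrix[, gene_a] == 1L
  b <- matrix[, gene_b] == 1L
  c(neither = sum(!a & !b), a_not_b = sum(a & !b),
    b_not_a = sum(!a & b), both = sum(a & b))
}

#' Fisher exact p-values for 2x2 tables
#'
#' Exact test p-values for tables given as the four counts
#' (neither, a_not_b, b_not_a, both). One-sided p-values are the
#' conditional hypergeometric tails (fixed margins), computed with
#' \code{stats::phyper} and vectorised over tables; "greater" tests
#' co-occurrence (P(X >= both)), "less" exclusivity (P(X <= both)).
#' "two.sided" delegates to \code{stats::fisher.test} per table.
#'
#' @param neither,a_not_b,b_not_a,both Non-negative integer vectors,
#'   recycled to a common length.
#' @param alternative "greater", "less" or "two.sided".
#' @return Numeric vector of p-values.
#' @export
fisher_exact_p <- function(neither, a_not_b, b_not_a, both,
                           alternative = c("greater", "less",
                                           "two.sided")) {
  alternative <- match.arg(alternative)
  n <- max(length(neither), length(a_not_b), length(b_not_a),
           length(both))
  neither <- rep_len(neither, n); a_not_b <- rep_len(a_not_b, n)
  b_not_a <- rep_len(b_not_a, n); both <- rep_len(both, n)
  N <- neither + a_not_b + b_not_a + both
  row1 <- both + a_not_b   # samples altered in gene A
  col1 <- both + b_not_a   # samples altered in gene B
  if (alternative == "greater") {
    stats::phyper(both - 1, col1, N - col1, row1, lower.tail = FALSE)
  } else if (alternative == "less") {
    stats::phyper(both, col1, N - col1, row1)
  } else {
    vapply(seq_len(n), function(i) {
      stats::fisher.test(matrix(c(both[i], a_not_b[i], b_not_a[i],
                                  neither[i]), nrow = 2L))$p.value
    }, numeric(1))
  }
}

#' Co-occurrence / mutual-exclusivity statistics for one pair
#'
#' From 2x2 counts computes the sample odds ratio
#' OR = (both * neither) / (a_not_b * b_not_a), its log2, a display form
#' following the cBioPortal convention (values above 3 print as ">3",
#' below -3 as "<-3", otherwise 3 decimals), the Fisher exact p-value and
#' the tendency call. When exactly the off-diagonal contains a zero with
#' \code{both > 0} the OR is +Inf and displays ">3".
#'
#' The default test is one-sided toward the observed direction
#' (co-occurrence tested with alternative "greater", exclusivity with
#' "less"), the convention of mutual-exclusivity modules; set
#' \code{sidedness = "two.sided"} for a two-sided test. With
#' \code{haldane = TRUE} a +0.5 continuity correction is added to all
#' four cells before computing the odds ratio (the p-value is always from
#' the uncorrected counts) — useful for zero-cell tables.
#'
#' @param counts Vector of four non-negative counts in the order
#'   (neither, a_not_b, b_not_a, both), as from [contingency()].
#' @param gene_a,gene_b Optional gene labels carried into the result.
#' @param sidedness "directional" (default) or "two.sided".
#' @param haldane Apply the Haldane-Anscombe +0.5 correction to the OR.
#' @return A one-row data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{neither}, \code{a_not_b}, \code{b_not_a}, \code{both},
#'   \code{odds_ratio}, \code{log2_odds_ratio}, \code{log2_display},
#'   \code{p}, \code{tendency}.
#' @examples
#' pair_stats(c(3715, 54, 272, 15))  # log2 OR 1.924, co-occurrence
#' @export
pair_stats <- function(counts, gene_a = "A", gene_b = "B",
                       sidedness = c("directional", "two.sided"),
                       haldane = FALSE) {
  sidedness <- match.arg(sidedness)
  counts <- as.numeric(counts)
  if (length(counts) != 4L || any(is.na(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("`counts` must be four non-negative integers", call. = FALSE)
  }
  neither <- counts[1L]; a_not_b <- counts[2L]
  b_not_a <- counts[3L]; both <- counts[4L]
  oc <- if (haldane) counts + 0.5 else counts
  num <- oc[4L] * oc[1L]
  den <- oc[2L] * oc[3L]
  odds_ratio <- if (den > 0) num / den else if (num > 0) Inf else NaN
  log2_or <- log2(odds_ratio)
  log2_display <- if (is.nan(odds_ratio)) {
    "NA"
  } else if (log2_or > 3) {
    ">3"
  } else if (log2_or < -3) {
    "<-3"
  } else {
    sprintf("%.3f", log2_or)
  }
  tendency <- if (is.nan(odds_ratio) || num == den) {
    "none"
  } else if (odds_ratio > 1) {
    "co-occurrence"
  } else {
    "mutual-exclusivity"
  }
  alternative <- if (sidedness == "two.sided") {
    "two.sided"
  } else if (tendency == "mutual-exclusivity") {
    "less"
  } else {
    "greater"
  }
  p <- fisher_exact_p(neither, a_not_b, b_not_a, both, alternative)
  data.frame(gene_a = gene_a, gene_b = gene_b,
             neither = neither, a_not_b = a_not_b, b_not_a = b_not_a,
             both = both, odds_ratio = odds_ratio,
             log2_odds_ratio = log2_or, log2_display = log2_display,
             p = p, tendency = tendency, stringsAsFactors = FALSE)
}

#' All-pairs co-occurrence analysis with BH correction
#'
#' Computes [pair_stats()] for every unordered pair of the given genes
#' and BH-adjusts the p-values across the pair family.
#'
#' @param matrix Binary alteration matrix.
#' @param gene_list Genes to analyse; default all columns. At least 2.
#' @inheritParams pair_stats
#' @return Data.frame of C(k, 2) rows sorted by p then gene pair, with a
#'   \code{q} column.
#' @export
all_pairs <- function(matrix, gene_list = colnames(matrix),
                      sidedness = c("directional", "two.sided"),
                      haldane = FALSE) {
  sidedness <- match.arg(sidedness)
  gene_list <- unique(as.character(gene_list))
  if (length(gene_list) < 2L) {
    stop("need at least 2 genes for pairwise analysis", call. = FALSE)
  }
  pairs <- utils::combn(sort(gene_list), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    pair_stats(contingency(matrix, a, b), gene_a = a, gene_b = b,
               sidedness = sidedness, haldane = haldane)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a co-occurrence results table
#'
#' Columns mirror the conventional report: gene pair, the four counts,
#' the capped log2 odds-ratio display, p, q and tendency.
#'
#' @param results Data.frame from [all_pairs()].
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_cooccurrence <- function(results, path) {
  cols <- c("gene_a", "gene_b", "neither", "a_not_b", "b_not_a", "both",
            "log2_display", "p", "q", "tendency")
  utils::write.table(results[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
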