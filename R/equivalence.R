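#' Pairwise target-set similarity of lncRNAs
#'
#' Structural equivalence of two lncRNAs is measured by the overlap of
#' their mRNA target sets. Supported metrics on sets A, B:
#' \itemize{
#'   \item jaccard (default): |A∩B| / |A∪B|
#'   \item dice: 2|A∩B| / (|A| + |B|)
#'   \item cosine: |A∩B| / sqrt(|A||B|)
#' }
#' Pairs where either set is empty score 0; the diagonal is 1 for
#' non-empty sets (0 for empty ones, so that sim = 1 always certifies
#' identical non-empty neighbourhoods).
#'
#' @param tsets Named list of target-ID vectors, as from [target_sets()].
#' @param metric "jaccard", "dice" or "cosine".
#' @return A symmetric numeric matrix with the lncRNA IDs as dimnames and
#'   a \code{"metric"} attribute.
#' @export
similarity_matrix <- function(tsets, metric = c("jaccard", "dice", "cosine")) {
  metric <- match.arg(metric)
  ids <- names(tsets)
  tsets <- lapply(tsets, unique)
  universe <- unique(unlist(tsets, use.names = FALSE))
  n <- length(tsets)
  # binary incidence; crossprod gives all pairwise intersection sizes
  inc <- matrix(0L, nrow = length(universe), ncol = n,
                dimnames = list(NULL, ids))
  for (j in seq_len(n)) inc[match(tsets[[j]], universe), j] <- 1L
  inter <- crossprod(inc)
  sizes <- vapply(tsets, length, integer(1))
  denom <- switch(metric,
    jaccard = outer(sizes, sizes, "+") - inter,
    dice    = outer(sizes, sizes, "+") / 2,
    cosine  = sqrt(outer(sizes, sizes))
  )
  sim <- ifelse(denom > 0, inter / denom, 0)
  dimnames(sim) <- list(ids, ids)
  attr(sim, "metric") <- metric
  sim
}

#' Hierarchical clustering of lncRNAs by target similarity
#'
#' Agglomerative clustering on the distance 1 - similarity. The result
#' is the usual \code{hclust} tree; use [dendrogram_newick()] to export
#' it for external viewers.
#'
#' @param sim Matrix from [similarity_matrix()].
#' @param linkage "average" (UPGMA, default), "complete" or "single".
#' @return An \code{hclust} object, or NULL with a warning when fewer
#'   than 2 lncRNAs are present.
#' @export
cluster_lncrnas <- function(sim, linkage = c("average", "complete",
                                             "single")) {
  linkage <- match.arg(linkage)
  if (nrow(sim) < 2L) {
    warning("fewer than 2 lncRNAs; no tree to build", call. = FALSE)
    return(NULL)
  }
  stats::hclust(stats::as.dist(1 - sim), method = linkage)
}

#' Newick export of a similarity dendrogram
#'
#' @param hc An \code{hclust} object from [cluster_lncrnas()].
#' @param path Optional file path; when given the tree is written there.
#' @return The Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Extract structurally equivalent groups
#'
#' Builds the graph whose vertices are the lncRNAs and whose edges join
#' pairs with similarity >= \code{threshold}, and returns its connected
#' components of size >= 2. Each group carries its mean within-group
#' pairwise similarity and the shared target core (the intersection of
#' all members' target sets).
#'
#' @param sim Matrix from [similarity_matrix()].
#' @param tsets The target sets the matrix was computed from.
#' @param threshold Similarity threshold in (0, 1].
#' @return List of groups, each a list with \code{member_ids} (sorted),
#'   \code{mean_within_similarity} and \code{shared_target_core}. Groups
#'   are ordered by decreasing size, then by first member ID.
#' @export
extract_groups <- function(sim, tsets, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  adj <- (sim >= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- Filter(function(m) length(m) >= 2L, groups)
  out <- lapply(groups, function(m) {
    m <- sort(m)
    s <- sim[m, m, drop = FALSE]
    list(
      member_ids = m,
      mean_within_similarity = mean(s[upper.tri(s)]),
      shared_target_core = sort(Reduce(intersect, tsets[m]))
    )
  })
  ord <- order(-vapply(out, function(g) length(g$member_ids), integer(1)),
               vapply(out, function(g) g$member_ids[1], character(1)))
  unname(out[ord])
}

#' Most similar pair of lncRNAs
#'
#' Argmax over off-diagonal similarities, optionally restricted to a
#' subset of IDs (e.g. the top-k ranked lncRNAs). Ties are broken
#' lexicographically on the sorted ID pair.
#'
#' @param sim Matrix from [similarity_matrix()].
#' @param restrict_to Optional character vector of IDs to restrict to.
#' @return List with \code{pair} (sorted ID pair) and \code{similarity}.
#' @export
most_similar_pair <- function(sim, restrict_to = NULL) {
  ids <- rownames(sim)
  if (!is.null(restrict_to)) {
    ids <- intersect(ids, restrict_to)
    sim <- sim[ids, ids, drop = FALSE]
  }
  if (length(ids) < 2L) {
    stop("need at least 2 lncRNAs to pick a most similar pair",
         call. = FALSE)
  }
  ut <- which(upper.tri(sim), arr.ind = TRUE)
  vals <- sim[ut]
  best <- which(vals == max(vals))
  pairs <- cbind(ids[ut[best, 1L]], ids[ut[best, 2L]])
  pairs <- t(apply(pairs, 1L, sort))
  ord <- order(pairs[, 1L], pairs[, 2L])
  list(pair = as.character(pairs[ord[1L], ]), similarity = max(vals))
}

#' Write a similarity matrix and its long form
#'
#' Writes the square matrix as TSV (IDs as first column and header) and,
#' optionally, a heatmap-ready long format (id1, id2, similarity) over
#' unordered pairs.
#'
#' @param sim Matrix from [similarity_matrix()].
#' @param path Output TSV path for the square matrix.
#' @param long_path Optional output path for the long format.
#' @return \code{path}, invisibly.
#' @export
write_similarity <- function(sim, path, long_path = NULL) {
  df <- data.frame(id = rownames(sim), as.data.frame(unclass(sim)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long_path)) {
    ut <- which(upper.tri(sim), arr.ind = TRUE)
    long <- data.frame(id1 = rownames(sim)[ut[, 1L]],
                       id2 = colnames(sim)[ut[, 2L]],
                       similarity = sim[ut], stringsAsFactors = FALSE)
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
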