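#' Gene-set collections (GMT)
#'
#' A collection is a named list of gene sets plus the universe used for
#' enrichment. The GMT dialect is one set per line:
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param sets Named list of character vectors (member gene IDs).
#' @param descriptions Optional character vector parallel to \code{sets}.
#' @param universe Optional universe; defaults to the union of all
#'   members. Members falling outside a supplied universe are dropped at
#'   construction (harmonisation).
#' @return Object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) && (is.null(names(sets)) || any(names(sets) == ""))) {
    stop("all gene sets must be named", call. = FALSE)
  }
  if (!length(sets)) names(sets) <- character(0)
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (is.null(universe)) {
    universe <- unique(unlist(sets, use.names = FALSE))
  } else {
    universe <- unique(as.character(universe))
    sets <- lapply(sets, intersect, universe)
  }
  structure(list(sets = sets,
                 descriptions = stats::setNames(descriptions, names(sets)),
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' @rdname gene_set_collection
#' @param path GMT file path.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(gene_set_collection(stats::setNames(list(), character(0))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) {
    stop("GMT line ", bad[1L], " has fewer than 2 fields", call. = FALSE)
  }
  names_ <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- names_
  gene_set_collection(sets, descriptions = desc)
}

#' @rdname gene_set_collection
#' @param collection A \code{gene_set_collection}.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of m * p_(j) / j,
#' capped at 1, returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be in [0, 1] with no NA", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' For a query gene set and every set in a collection, tests whether the
#' overlap k is larger than expected by chance under sampling without
#' replacement from the universe: with N = universe size, K = set size,
#' n = query size (after harmonisation), p = P(X >= k) for
#' X ~ Hypergeometric(N, K, n). The observed k is included in the tail
#' (standard ORA convention). BH adjustment is applied across all sets
#' in the collection; results are sorted by p then set name.
#'
#' @param query Character vector of gene IDs. IDs outside the collection
#'   universe are dropped with a message reporting the count.
#' @param collection A \code{gene_set_collection}. Choose the universe
#'   deliberately (all collection genes, all significant mRNAs, all
#'   network mRNAs, ...): it materially changes p.
#' @return Data.frame with columns \code{set}, \code{k}, \code{n},
#'   \code{K}, \code{N}, \code{p}, \code{q}.
#' @export
ora <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  N <- length(collection$universe)
  if (N == 0L) stop("empty universe", call. = FALSE)
  query <- unique(as.character(query))
  inside <- query %in% collection$universe
  if (any(!inside)) {
    message("ora: dropping ", sum(!inside),
            " query gene(s) outside the universe")
  }
  query <- query[inside]
  n <- length(query)
  if (n == 0L) {
    warning("empty query after harmonisation; no enrichment computed",
            call. = FALSE)
    return(data.frame(set = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  }
  K <- vapply(collection$sets, length, integer(1))
  k <- vapply(collection$sets, function(s) length(intersect(query, s)),
              integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set = names(collection$sets), k = as.integer(k),
                    n = n, K = as.integer(K), N = N, p = p,
                    q = bh_adjust(p), stringsAsFactors = FALSE)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway overlay of a regulatory network
#'
#' Restricts the network to the edges whose mRNA belongs to a pathway
#' gene set (matching on mRNA symbol, falling back to ID) and, optionally,
#' to a subset of lncRNAs — the edge list a pathway diagram would be
#' annotated with, plus participation counts.
#'
#' @param network A \code{regulatory_network}.
#' @param pathway_genes Character vector of pathway member genes
#'   (symbols or IDs).
#' @param lncrna_subset Optional character vector of lncRNA IDs to
#'   restrict to (e.g. the top-ranked set).
#' @param pathway_name Label carried into the output.
#' @return List with \code{pathway_name}, \code{edges} (lncrna_id,
#'   lncrna_symbol, gene, direction of the target), \code{lncrna_targets}
#'   (list mapping participating lncRNA to its targeted pathway genes),
#'   \code{participating_lncrna_count}, \code{targeted_gene_count}.
#' @export
overlay <- function(network, pathway_genes, lncrna_subset = NULL,
                    pathway_name = "pathway") {
  stopifnot(inherits(network, "regulatory_network"))
  if (!length(pathway_genes)) stop("empty pathway", call. = FALSE)
  mi <- match(network$edges$mrna_id, network$mrna_nodes$id)
  gene_label <- network$mrna_nodes$symbol[mi]
  gene_label[is.na(gene_label) | gene_label == ""] <-
    network$edges$mrna_id[is.na(gene_label) | gene_label == ""]
  keep <- gene_label %in% pathway_genes |
    network$edges$mrna_id %in% pathway_genes
  if (!is.null(lncrna_subset)) {
    keep <- keep & network$edges$lncrna_id %in% lncrna_subset
  }
  e <- network$edges[keep, , drop = FALSE]
  genes <- gene_label[keep]
  li <- match(e$lncrna_id, network$lncrna_nodes$id)
  mi2 <- match(e$mrna_id, network$mrna_nodes$id)
  edges <- data.frame(
    lncrna_id = e$lncrna_id,
    lncrna_symbol = network$lncrna_nodes$symbol[li],
    gene = genes,
    direction = network$mrna_nodes$direction[mi2],
    pathway = rep(pathway_name, nrow(e)),
    stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL
  list(
    pathway_name = pathway_name,
    edges = edges,
    lncrna_targets = lapply(split(edges$gene, edges$lncrna_id),
                            function(g) sort(unique(g))),
    participating_lncrna_count = length(unique(edges$lncrna_id)),
    targeted_gene_count = length(unique(edges$gene))
  )
}

#' Write an ORA result table
#'
#' @param results Data.frame from [ora()].
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_ora <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
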