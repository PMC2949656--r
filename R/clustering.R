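# Agglomerative hierarchical clustering of samples or genes with Ward
# linkage on 1 - Pearson correlation, plus branch extraction and
# cluster-vs-label association testing.

#' 1 - Pearson correlation dissimilarity
#'
#' @param X log2 expression matrix (probes x samples).
#' @param axis `"samples"` (columns, the default) or `"genes"` (rows).
#' @return A `dist` object with entries `1 - r`, range `[0, 2]`.
#' @export
correlation_distance <- function(X, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  M <- if (axis == "samples") X else t(X)
  if (ncol(M) < 2L) stop("need at least two items to compute distances")
  sds <- apply(M, 2L, stats::sd)
  if (any(zero <- sds == 0 | is.na(sds)))
    stop("zero-variance vector(s): ",
         paste(utils::head(colnames(M)[zero], 5L), collapse = ", "),
         call. = FALSE)
  stats::as.dist(1 - stats::cor(M))
}

#' Ward agglomerative clustering of a dissimilarity matrix
#'
#' Applies the Lance-Williams Ward recurrence directly to the dissimilarity
#' as given (the historical default of early clustering tools). Set
#' `squared = TRUE` for the variant that squares dissimilarities before the
#' recurrence and reports square-rooted heights.
#'
#' @param D `dist` object or square symmetric matrix.
#' @param squared use the squared-dissimilarity Ward dialect.
#' @return An `hclust` tree.
#' @export
ward_cluster <- function(D, squared = FALSE) {
  if (is.matrix(D)) {
    if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
      stop("dissimilarity matrix must be square and symmetric")
    D <- stats::as.dist(D)
  }
  if (!inherits(D, "dist")) stop("D must be a dist object or square matrix")
  stats::hclust(D, method = if (squared) "ward.D2" else "ward.D")
}

#' Cut a dendrogram into k clusters
#'
#' Labels are induced by removing the `k - 1` highest merges; clusters are
#' renumbered 1..k by the index of their first member, making the numbering
#' stable across runs.
#'
#' @param tree `hclust` object.
#' @param k number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels named by item.
#' @export
cut_dendrogram <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k must be between 1 and the number of leaves")
  raw <- stats::cutree(tree, k = k)
  # renumber by first-member index so numbering is stable across runs
  stats::setNames(match(raw, unique(raw)), names(raw))
}

#' Test association between cluster labels and an external classification
#'
#' Pearson chi-square test of independence on the r x c contingency table;
#' for 2 x 2 tables with any expected count below 5 the two-sided Fisher
#' exact test is used instead.
#'
#' @param labels,classes two categorical vectors of equal length.
#' @return list with `statistic`, `p_value`, `test_used` and `table`.
#' @export
cluster_class_association <- function(labels, classes) {
  if (length(labels) != length(classes)) stop("vectors must have equal length")
  tab <- table(labels, classes)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("association test is degenerate: a vector has a single category")
  contingency_test(tab)
}
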