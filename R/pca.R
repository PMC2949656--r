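# Two-component PCA visualisation of tumours in a chosen gene space, and
# model-based (Gaussian mixture) confirmation of visually identified groups.

#' PCA scores of samples restricted to a gene list
#'
#' Column-centered covariance PCA (no per-gene standardisation) by singular
#' value decomposition of the samples-by-genes matrix. Component signs are
#' fixed by making each component's largest-magnitude gene loading positive,
#' so results are fully deterministic.
#'
#' @param X log2 expression matrix (probes/genes x samples).
#' @param genes row ids to use; ids absent from `X` are dropped with a
#'   warning.
#' @param k number of components (default 2).
#' @param scale. standardise genes to unit variance before PCA.
#' @return list with `scores` (samples x k), `explained` (variance
#'   fractions), `loadings` (genes x k) and `genes_used`.
#' @export
pca_scores <- function(X, genes, k = 2L, scale. = FALSE) {
  missing_genes <- setdiff(genes, rownames(X))
  if (length(missing_genes)) {
    warning("dropping ", length(missing_genes), " gene(s) absent from the matrix: ",
            paste(utils::head(missing_genes, 5L), collapse = ", "))
    genes <- intersect(genes, rownames(X))
  }
  if (length(genes) < 2L) stop("fewer than two usable genes for PCA")
  M <- t(X[genes, , drop = FALSE])              # samples x genes
  pc <- stats::prcomp(M, center = TRUE, scale. = scale.)
  k <- min(k, ncol(pc$rotation))
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1L))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, explained = expl[seq_len(k)],
       loadings = loadings, genes_used = genes)
}

#' Gaussian-mixture clustering of PCA scores
#'
#' Fits Gaussian mixtures by expectation-maximisation for each candidate
#' number of components and keeps the best-BIC model; used to confirm groups
#' identified visually on the first two principal components.
#'
#' @param scores numeric matrix (samples x dimensions).
#' @param k_range candidate component counts (default 1..5).
#' @param seed RNG seed (EM initialisation is deterministic, but a seed is
#'   taken for reproducibility of any stochastic model variants).
#' @return list with `labels`, `k`, and the per-k `bic` table.
#' @importFrom mclust Mclust mclustBIC
#' @export
gmm_cluster <- function(scores, k_range = 1:5, seed = 1L) {
  if (nrow(scores) < max(k_range))
    stop("need at least max(k_range) points")
  set.seed(seed)
  bic <- mclust::mclustBIC(scores, G = k_range, verbose = FALSE)
  fit <- mclust::Mclust(scores, x = bic, verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  list(labels = fit$classification, k = as.integer(fit$G), bic = fit$BIC)
}
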