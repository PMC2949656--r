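# Nearest-centroid assignment of samples to intrinsic breast-cancer
# subtypes: probes are matched to centroid genes in the declared identifier
# namespace, collapsed to one row per gene, and each sample is assigned to
# the subtype whose centroid has the largest Pearson correlation.

.namespace_column <- c(symbol = "gene_symbol", unigene = "unigene_id",
                       entrez = "entrez_id")

#' Match expression probes to centroid genes
#'
#' Maps probes to centroid genes through the annotation column named by the
#' centroid file's identifier namespace. Genes matched by several probes are
#' collapsed by the mean of the probe rows; centroid genes with no matching
#' probe are dropped and counted.
#'
#' @param X log2 expression matrix (probes x samples).
#' @param annotation probe annotation data.frame.
#' @param centroids gene-by-subtype matrix with a `"namespace"` attribute
#'   (see [read_centroids()]).
#' @return list with `expression` (gene-by-sample matrix over common genes),
#'   `n_common_genes`, and `n_unmatched` centroid genes.
#' @export
match_features <- function(X, annotation, centroids) {
  ns <- attr(centroids, "namespace")
  if (is.null(ns) || !ns %in% names(.namespace_column))
    stop("centroids must declare a namespace of symbol, unigene or entrez")
  col <- .namespace_column[[ns]]
  ann <- annotation[match(rownames(X), annotation$probe_id), ]
  ids <- as.character(ann[[col]])
  ids[is.na(ids)] <- ""
  common <- intersect(rownames(centroids), ids[nzchar(ids)])
  if (length(common) == 0L)
    stop("no common genes between expression annotation and centroids")
  rows <- lapply(common, function(g) {
    idx <- which(ids == g)
    if (length(idx) == 1L) X[idx, ] else colMeans(X[idx, , drop = FALSE])
  })
  expr <- do.call(rbind, rows)
  rownames(expr) <- common
  list(expression = expr,
       n_common_genes = length(common),
       n_unmatched = nrow(centroids) - length(common))
}

#' Assign samples to intrinsic subtypes by centroid correlation
#'
#' Computes, over the matched genes, the Pearson correlation between each
#' sample and each subtype centroid and assigns the subtype with the largest
#' coefficient. With `center = "median"` (the default, the usual convention
#' for single-channel data) each matched gene is first median-centered
#' across the cohort.
#'
#' @param X log2 expression matrix.
#' @param annotation probe annotation.
#' @param centroids centroid matrix (see [read_centroids()]).
#' @param center `"median"` or `"none"`.
#' @param min_r optional minimum correlation; below it a sample is labelled
#'   `"unclassified"`. Default `NULL` assigns every sample.
#' @return data.frame with one row per sample: `sample_id`, `subtype`, one
#'   `r_<subtype>` column per centroid, `n_common_genes` and `tie_flag`
#'   (exact ties resolved to the alphabetically first subtype).
#' @export
assign_subtypes <- function(X, annotation, centroids,
                            center = c("median", "none"), min_r = NULL) {
  center <- match.arg(center)
  matched <- match_features(X, annotation, centroids)
  expr <- matched$expression
  if (nrow(expr) < 2L) stop("fewer than two matched genes")
  if (center == "median")
    expr <- expr - apply(expr, 1L, stats::median)
  cent <- centroids[rownames(expr), , drop = FALSE]
  r <- stats::cor(expr, cent)                      # samples x subtypes
  ord <- order(colnames(cent))                     # alphabetical tie-break
  best <- apply(r[, ord, drop = FALSE], 1L, which.max)
  subtype <- colnames(cent)[ord][best]
  maxr <- r[cbind(seq_len(nrow(r)), match(subtype, colnames(r)))]
  tie <- apply(r, 1L, function(z) sum(z == max(z)) > 1L)
  if (!is.null(min_r)) subtype[maxr < min_r] <- "unclassified"
  out <- data.frame(sample_id = colnames(X), subtype = subtype,
                    stringsAsFactors = FALSE, row.names = NULL)
  rcols <- as.data.frame(r)
  colnames(rcols) <- paste0("r_", colnames(cent))
  out <- cbind(out, rcols, row.names = NULL)
  out$n_common_genes <- matched$n_common_genes
  out$tie_flag <- tie
  out
}
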