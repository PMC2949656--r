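# Static figures: clustered heatmap and PCA scatter.

#' Clustered expression heatmap
#'
#' Orders genes and samples by their Ward/1-Pearson dendrogram leaf order
#' and draws a log2-expression image, the display convention of the
#' unsupervised analysis.
#'
#' @param X log2 expression matrix (probes x samples).
#' @param file optional PNG path.
#' @param main title.
#' @return invisibly, the list of the two `hclust` trees.
#' @export
expression_heatmap <- function(X, file = NULL, main = "Expression heatmap") {
  st <- ward_cluster(correlation_distance(X, "samples"))
  gt <- ward_cluster(correlation_distance(X, "genes"))
  M <- X[gt$order, st$order, drop = FALSE]
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900)
    on.exit(grDevices::dev.off())
  }
  cols <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  graphics::image(t(M), col = cols, axes = FALSE, main = main)
  invisible(list(sample_tree = st, gene_tree = gt))
}

#' Scatter plot of the first two principal components
#'
#' @param projection result of [pca_scores()].
#' @param labels optional point labels used for colouring.
#' @param file optional PNG path.
#' @param main title.
#' @export
pca_plot <- function(projection, labels = NULL, file = NULL,
                     main = "PCA of samples") {
  s <- projection$scores
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 700)
    on.exit(grDevices::dev.off())
  }
  col <- if (is.null(labels)) "black" else as.integer(factor(labels)) + 1L
  graphics::plot(s[, 1L], s[, 2L], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * projection$explained[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * projection$explained[2L]),
                 main = main)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_len(nlevels(factor(labels))) + 1L, pch = 19,
                     cex = 0.8)
  invisible(NULL)
}

#' Export a dendrogram in Newick format
#'
#' @param tree an `hclust` object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export needs the 'ape' package")
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
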