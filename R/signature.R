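# Supervised signature derivation for a two-group contrast: per-probe Welch
# t-test, local false-discovery-rate estimation on the probit scale, and
# random-forest permutation-importance selection of a fixed-size signature.

#' Welch two-sample t-test
#'
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided Student-t p-value.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df` and `p`.
#' @export
welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("welch_t needs at least two values per group")
  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df = df)
  list(t = t, df = df, p = p)
}

# Vectorised Welch t over matrix rows; ia, ib are column indices.
.row_welch_t <- function(X, ia, ib) {
  A <- X[, ia, drop = FALSE]; B <- X[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- (rowSums(A * A) - na * ma * ma) / (na - 1) / na
  vb <- (rowSums(B * B) - nb * mb * mb) / (nb - 1) / nb
  t <- (ma - mb) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df = df)
  data.frame(t_statistic = t, welch_df = df, p_value = p)
}

#' Local false-discovery-rate estimation from p-values
#'
#' Transforms p-values to the probit scale (`z = qnorm(p)`) and fits the
#' two-component mixture `f(z) = pi0 * phi(z) + (1 - pi0) * f1(z)` with a
#' theoretical N(0,1) null and `f1` a Gaussian-kernel density re-estimated
#' iteratively from the posterior non-null weights. `lfdr(z) =
#' pi0 * phi(z) / f(z)`, clipped to `[0, 1]`. `pi0` is estimated from the
#' fraction of p-values above 1/2.
#'
#' @param p_values vector of p-values; values outside `(0, 1)` are clamped
#'   to machine-epsilon bounds and counted in `n_clamped`.
#' @param n_iter maximum f1 refinement iterations.
#' @param tol convergence tolerance on the mean absolute lfdr change.
#' @return list with `lfdr`, `pi0`, `degenerate` flag and `n_clamped`.
#' @export
local_fdr <- function(p_values, n_iter = 30L, tol = 1e-5) {
  eps <- .Machine$double.eps
  clamped <- p_values <= 0 | p_values >= 1 | !is.finite(p_values)
  p <- pmin(pmax(p_values, eps), 1 - eps)
  n <- length(p)
  z <- stats::qnorm(p)
  f0 <- stats::dnorm(z)
  pi0 <- min(1, mean(p > 0.5) / 0.5)
  if (stats::sd(z) < 1e-8 || pi0 >= 1 - 1e-8) {
    # no usable signal: everything is attributed to the null
    return(list(lfdr = rep(1, n), pi0 = 1,
                degenerate = stats::sd(z) < 1e-8, n_clamped = sum(clamped)))
  }
  lfdr <- rep(pi0, n)
  for (it in seq_len(n_iter)) {
    w1 <- 1 - lfdr
    sw <- sum(w1)
    if (sw < 1) { lfdr <- rep(1, n); pi0 <- 1; break }
    dens <- stats::density(z, weights = w1 / sw, bw = stats::bw.nrd0(z),
                           n = 1024L, from = min(z) - 1, to = max(z) + 1)
    f1 <- stats::approx(dens$x, dens$y, xout = z, rule = 2L)$y
    f <- pmax(pi0 * f0 + (1 - pi0) * f1, 1e-300)
    new <- pmin(1, pi0 * f0 / f)
    delta <- mean(abs(new - lfdr))
    lfdr <- new
    if (delta < tol) break
  }
  list(lfdr = lfdr, pi0 = pi0, degenerate = FALSE, n_clamped = sum(clamped))
}

#' Random-forest selection of discriminating probes
#'
#' Fits a random-forest classifier on the candidate probes and ranks them by
#' unscaled permutation importance on out-of-bag samples; the top `n_keep`
#' are returned. Fully determined by `seed`.
#'
#' @param X log2 expression matrix.
#' @param groups factor-like vector of two group labels, one per sample.
#' @param candidates probe ids to rank (subset of `rownames(X)`).
#' @param n_keep number of probes to keep (default 200).
#' @param n_trees number of trees (default 1000).
#' @param seed mandatory RNG seed.
#' @param importance_p optionally filter by a permutation p-value on the
#'   importance (importance vs `n_perm` label permutations); probes with
#'   p >= `importance_p` are dropped before taking the top `n_keep`.
#' @param n_perm label permutations used when `importance_p` is set.
#' @return data.frame ranked by decreasing importance: `probe_id`,
#'   `importance`, `rank`, `selected`.
#' @export
forest_select <- function(X, groups, candidates, n_keep = 200L,
                          n_trees = 1000L, seed, importance_p = NULL,
                          n_perm = 50L) {
  if (missing(seed)) stop("forest_select requires an explicit seed")
  stopifnot(all(candidates %in% rownames(X)))
  y <- factor(groups)
  if (nlevels(y) != 2L) stop("forest_select needs exactly two groups")
  if (n_keep > length(candidates)) {
    warning("n_keep exceeds the number of candidates; returning all")
    n_keep <- length(candidates)
  }
  feat <- t(X[candidates, , drop = FALSE])
  # canonical orientation: the ranking depends on the sample partition only,
  # not on which group is named first
  y <- factor(ifelse(y == y[1L], "g1", "g2"), levels = c("g1", "g2"))
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = feat, y = y, ntree = n_trees,
    mtry = max(1L, floor(sqrt(length(candidates)))),
    importance = TRUE)
  imp <- randomForest::importance(rf, type = 1L, scale = FALSE)[, 1L]
  keep_mask <- rep(TRUE, length(imp))
  if (!is.null(importance_p)) {
    null_max <- replicate(n_perm, {
      yp <- sample(y)
      rfp <- randomForest::randomForest(
        x = feat, y = yp, ntree = max(100L, n_trees %/% 10L),
        mtry = max(1L, floor(sqrt(length(candidates)))), importance = TRUE)
      randomForest::importance(rfp, type = 1L, scale = FALSE)[, 1L]
    })
    pv <- vapply(seq_along(imp),
                 function(i) (sum(null_max[i, ] >= imp[i]) + 1) / (n_perm + 1),
                 numeric(1L))
    keep_mask <- pv < importance_p
  }
  ord <- order(-imp, candidates)      # deterministic tie-break by probe id
  out <- data.frame(probe_id = candidates[ord], importance = imp[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE,
                    row.names = NULL)
  out$selected <- keep_mask[ord] & cumsum(keep_mask[ord]) <= n_keep
  out
}

#' Derive a two-group expression signature
#'
#' Screens probes by a per-probe Welch t-test (`p < p_thresh`), reports the
#' local FDR achieved at the screen boundary, then ranks the screened probes
#' with a random forest and keeps the top `n_keep` as the signature.
#' Directions (`up`/`down`, relative to group A) come from the sign of t.
#'
#' @param X log2 expression matrix (typically after the intensity filter).
#' @param groups vector of two labels, one per sample; group A is the first
#'   level (alphabetically unless `groups` is a factor).
#' @param annotation optional probe annotation for gene-level lists.
#' @param p_thresh Welch p screen threshold (default 0.01).
#' @param n_keep signature size (default 200).
#' @param n_trees random-forest size (default 1000).
#' @param seed mandatory RNG seed for the forest.
#' @param importance_p optional permutation-importance p filter, see
#'   [forest_select()].
#' @return `signature_result`: list with `contrast`, `screen_size`,
#'   `lfdr_at_screen` (largest local FDR among screened probes), `pi0`,
#'   `selected` probe ids, per-probe `stats` table, and gene-level
#'   `genes_up`/`genes_down` (plus `screen_genes_up`/`screen_genes_down`)
#'   when an annotation is given.
#' @export
derive_signature <- function(X, groups, annotation = NULL, p_thresh = 0.01,
                             n_keep = 200L, n_trees = 1000L, seed,
                             importance_p = NULL) {
  if (missing(seed)) stop("derive_signature requires an explicit seed")
  y <- factor(groups)
  if (nlevels(y) != 2L) stop("groups must define exactly two classes")
  ia <- which(y == levels(y)[1L]); ib <- which(y == levels(y)[2L])
  if (min(length(ia), length(ib)) < 4L)
    warning("very small group (n < 4): Welch df may drop below 2; interpret with caution")
  st <- .row_welch_t(X, ia, ib)
  st <- cbind(data.frame(probe_id = rownames(X), stringsAsFactors = FALSE), st)
  lf <- local_fdr(st$p_value)
  st$local_fdr <- lf$lfdr
  st$direction <- ifelse(st$t_statistic >= 0, "up", "down")
  screen <- st$probe_id[st$p_value < p_thresh]
  if (length(screen) == 0L) stop("no probes pass the screen")
  lfdr_at_screen <- max(st$local_fdr[st$p_value < p_thresh])
  rf <- forest_select(X, y, screen, n_keep = n_keep, n_trees = n_trees,
                      seed = seed, importance_p = importance_p)
  st$importance <- rf$importance[match(st$probe_id, rf$probe_id)]
  st$selected <- st$probe_id %in% rf$probe_id[rf$selected]
  sel <- st[st$selected, ]
  res <- list(contrast = paste(levels(y), collapse = " vs "),
              screen_size = length(screen),
              lfdr_at_screen = lfdr_at_screen,
              pi0 = lf$pi0,
              selected = rf$probe_id[rf$selected],
              stats = st)
  if (!is.null(annotation)) {
    sym <- function(ids) {
      g <- annotation$gene_symbol[match(ids, annotation$probe_id)]
      unique(g[!is.na(g) & nzchar(g)])
    }
    scr <- st[st$p_value < p_thresh, ]
    res$genes_up <- sym(sel$probe_id[sel$direction == "up"])
    res$genes_down <- sym(sel$probe_id[sel$direction == "down"])
    res$screen_genes_up <- sym(scr$probe_id[scr$direction == "up"])
    res$screen_genes_down <- sym(scr$probe_id[scr$direction == "down"])
  }
  class(res) <- "signature_result"
  res
}

#' @export
print.signature_result <- function(x, ...) {
  cat("Signature:", x$contrast, "\n")
  cat(sprintf("  screened probes (Welch p): %d (local FDR at boundary %.3f, pi0 %.3f)\n",
              x$screen_size, x$lfdr_at_screen, x$pi0))
  cat(sprintf("  selected probes:           %d\n", length(x$selected)))
  if (!is.null(x$genes_up))
    cat(sprintf("  genes up/down:             %d / %d\n",
                length(x$genes_up), length(x$genes_down)))
  invisible(x)
}
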