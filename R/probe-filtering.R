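# Probe-set selection for unsupervised analysis: intensity floor, chi-square
# variance test against the median variance, and a robust coefficient of
# variation window. Percentiles use linear interpolation between order
# statistics (quantile type 7) throughout.

.row_vars <- function(X) {
  n <- ncol(X)
  m <- rowMeans(X)
  (rowSums(X * X) - n * m * m) / (n - 1)
}

#' Intensity filter for probe sets
#'
#' Removes control probes and probes whose 90th-percentile log2 intensity
#' falls below a floor; only consistently expressed probes are kept.
#'
#' @param X log2 expression matrix (probes x samples).
#' @param annotation optional probe annotation with `is_control`; control
#'   probes are removed when provided.
#' @param percentile per-probe intensity percentile inspected (default 90).
#' @param min_log2 minimum value of that percentile for a probe to be kept.
#' @return Character vector of retained probe ids, in input order.
#' @export
intensity_filter <- function(X, annotation = NULL, percentile = 90,
                             min_log2 = 10) {
  validate_expression_matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty expression matrix")
  q <- apply(X, 1L, stats::quantile, probs = percentile / 100,
             na.rm = TRUE, names = FALSE, type = 7)
  keep <- q >= min_log2
  if (!is.null(annotation)) {
    ctrl <- annotation$probe_id[annotation$is_control %in% TRUE]
    keep <- keep & !(rownames(X) %in% ctrl)
  }
  rownames(X)[keep]
}

#' Chi-square variance test for a single probe
#'
#' Tests whether a probe's variance across samples differs from a reference
#' variance (here, the cohort-wide median of probe variances). The statistic
#' is `(n-1) * Var(values) / varmed`, referred to the chi-square distribution
#' with `n-1` degrees of freedom. Variances use the unbiased `n-1`
#' denominator, consistent with `(n-1) Var / sigma^2 ~ chi-square(n-1)`.
#'
#' @param values numeric vector (one probe across samples), `n >= 2`.
#' @param varmed reference variance, `> 0`.
#' @param two_sided if `TRUE`, p is twice the smaller tail; the default is
#'   the upper tail, matching selection of high-variability probes.
#' @return list with `statistic` and `p_value`.
#' @export
variance_test <- function(values, varmed, two_sided = FALSE) {
  if (length(values) < 2L) stop("variance test needs n >= 2")
  if (!is.finite(varmed) || varmed <= 0) stop("varmed must be > 0")
  n <- length(values)
  stat <- (n - 1) * stats::var(values) / varmed
  up <- stats::pchisq(stat, df = n - 1, lower.tail = FALSE)
  p <- if (two_sided) min(1, 2 * min(up, 1 - up)) else up
  list(statistic = stat, p_value = p)
}

# Vectorised variance test over the rows of a matrix.
.row_variance_test <- function(X, varmed, two_sided = FALSE) {
  n <- ncol(X)
  stat <- (n - 1) * .row_vars(X) / varmed
  up <- stats::pchisq(stat, df = n - 1, lower.tail = FALSE)
  p <- if (two_sided) pmin(1, 2 * pmin(up, 1 - up)) else up
  data.frame(statistic = stat, p_value = p)
}

#' Robust coefficient of variation
#'
#' Orders the values, removes exactly one minimum and one maximum occurrence
#' (also under ties), and returns the coefficient of variation (sample SD /
#' mean) of the remainder.
#'
#' @param values numeric vector with `n >= 4` so that at least two values
#'   remain after trimming.
#' @return rCV, or `NA` (flagged undefined) when the trimmed mean is zero.
#' @export
robust_cv <- function(values) {
  if (length(values) < 4L) stop("robust_cv needs n >= 4")
  s <- sort(values)
  trimmed <- s[-c(1L, length(s))]
  m <- mean(trimmed)
  if (m == 0) return(NA_real_)
  stats::sd(trimmed) / m
}

# Vectorised rCV using sums minus one min and one max instance per row.
.row_robust_cv <- function(X) {
  n <- ncol(X)
  if (n < 4L) stop("robust_cv needs n >= 4")
  mn <- apply(X, 1L, min)
  mx <- apply(X, 1L, max)
  k <- n - 2L
  s1 <- rowSums(X) - mn - mx
  s2 <- rowSums(X * X) - mn * mn - mx * mx
  m <- s1 / k
  v <- pmax(0, (s2 - k * m * m) / (k - 1))
  ifelse(m == 0, NA_real_, sqrt(v) / m)
}

#' Select highly variable probes for clustering
#'
#' Applies, in order: the intensity/control filter (optional), the
#' chi-square variance test against the median of all probe variances
#' (computed over the intensity-filtered input, before any selection), and
#' an rCV window keeping probes whose rCV lies strictly between the
#' collection's `rcv_percentile` quantile and `rcv_cap`.
#'
#' @param X log2 expression matrix.
#' @param annotation optional probe annotation (control flags).
#' @param p_thresh variance-test p-value threshold (default 0.01).
#' @param rcv_cap upper rCV bound (default 10, plain ratio scale).
#' @param rcv_percentile lower rCV bound as a percentile of all rCVs
#'   (default 95).
#' @param apply_intensity run [intensity_filter()] internally (default TRUE).
#' @param percentile,min_log2 passed to [intensity_filter()].
#' @param two_sided passed to [variance_test()].
#' @return list with `probes` (selected ids) and `report`, a `filter_report`
#'   holding the monotone count chain and the per-probe statistics.
#' @export
select_clustering_probes <- function(X, annotation = NULL, p_thresh = 0.01,
                                     rcv_cap = 10, rcv_percentile = 95,
                                     apply_intensity = TRUE,
                                     percentile = 90, min_log2 = 10,
                                     two_sided = FALSE) {
  validate_expression_matrix(X)
  n_input <- nrow(X)
  if (apply_intensity) {
    keep <- intensity_filter(X, annotation, percentile, min_log2)
    X <- X[keep, , drop = FALSE]
  }
  n_intensity <- nrow(X)
  if (n_intensity == 0L) stop("no probes survive the intensity filter")

  vars <- .row_vars(X)
  varmed <- stats::median(vars)
  if (varmed <= 0) stop("median probe variance is not positive")
  vt <- .row_variance_test(X, varmed, two_sided)
  rcv <- .row_robust_cv(X)
  rcv_lo <- stats::quantile(rcv, probs = rcv_percentile / 100,
                            na.rm = TRUE, names = FALSE, type = 7)

  pass_var <- vt$p_value < p_thresh
  pass_rcv <- !is.na(rcv) & rcv > rcv_lo & rcv < rcv_cap
  kept <- pass_var & pass_rcv

  per_probe <- data.frame(probe_id = rownames(X), variance = vars,
                          statistic = vt$statistic, p_value = vt$p_value,
                          rcv = rcv, pass_variance = pass_var,
                          pass_rcv = pass_rcv, kept = kept,
                          stringsAsFactors = FALSE, row.names = NULL)
  report <- structure(list(
    n_input = n_input,
    n_after_intensity = n_intensity,
    n_after_variance = sum(pass_var),
    n_after_rcv = sum(kept),
    varmed = varmed,
    rcv_lower = rcv_lo,
    thresholds = list(p_thresh = p_thresh, rcv_cap = rcv_cap,
                      rcv_percentile = rcv_percentile,
                      intensity_percentile = percentile,
                      min_log2 = min_log2, two_sided = two_sided,
                      quantile_type = 7L),
    per_probe = per_probe), class = "filter_report")
  list(probes = per_probe$probe_id[kept], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Probe filter report\n")
  cat(sprintf("  input probes:          %d\n", x$n_input))
  cat(sprintf("  after intensity filter: %d\n", x$n_after_intensity))
  cat(sprintf("  variance test p < %g:   %d\n",
              x$thresholds$p_thresh, x$n_after_variance))
  cat(sprintf("  after rCV window:       %d selected\n", x$n_after_rcv))
  invisible(x)
}
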