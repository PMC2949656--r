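# Immunohistochemistry scoring and contingency analysis: the 0/1/2 scoring
# rule, per-marker positivity, marker-by-group counts, and chi-square /
# Fisher exact association tests.

.ihc_panel <- c("AR", "ER", "PR", "ERBB2", "GCDFP15", "GGT1", "PTEN", "EGFR")

#' IHC score from the percentage of positive tumour cells
#'
#' Score 0: no positive tumour cells; score 1: 1-10% positive; score 2:
#' 11-100% positive, regardless of stain intensity.
#'
#' @param percent_positive percentage in `[0, 100]`.
#' @return Integer score 0, 1 or 2.
#' @export
score_from_percent <- function(percent_positive) {
  if (any(percent_positive < 0 | percent_positive > 100, na.rm = TRUE))
    stop("percent_positive must lie in [0, 100]")
  ifelse(percent_positive == 0, 0L,
         ifelse(percent_positive <= 10, 1L, 2L))
}

#' Marker positivity from an IHC score
#'
#' Hormone receptors (ER, PR, AR) are positive only at score 2; the
#' apocrine/pathway markers (GGT1, GCDFP15, EGFR, PTEN) are positive from
#' score 1 up (any staining above 1% of cells); ERBB2 positivity follows the
#' Herceptest reading (by default only `+++` is positive).
#'
#' @param marker marker name from the panel AR, ER, PR, ERBB2, GCDFP15,
#'   GGT1, PTEN, EGFR.
#' @param score 0/1/2 score (ignored for ERBB2).
#' @param herceptest Herceptest string (`"0"`, `"+"`, `"++"`, `"+++"`),
#'   required for ERBB2; `"nd"`/`NA` gives `NA` (not evaluable).
#' @param erbb2_positive Herceptest readings counted positive.
#' @return Logical: positive (`TRUE`), negative (`FALSE`) or `NA`.
#' @export
positivity <- function(marker, score = NA, herceptest = NA,
                       erbb2_positive = "+++") {
  if (!marker %in% .ihc_panel) stop("unknown marker: ", marker)
  if (marker == "ERBB2") {
    if (is.na(herceptest) || herceptest == "nd") return(NA)
    return(herceptest %in% erbb2_positive)
  }
  if (is.na(score)) return(NA)
  if (marker %in% c("ER", "PR", "AR")) score >= 2 else score >= 1
}

#' Positive / total counts for a marker within a group
#'
#' Applies the positivity rule to the rows of an IHC score table; rows with
#' a missing (`nd`) reading are excluded from the denominator.
#'
#' @param table IHC table (see [read_ihc_table()]); Cowden tumours are the
#'   rows with `cowden_disease == "Yes"`.
#' @param marker marker column name.
#' @param group `"cowden"`, `"non_cowden"`, or `"all"`.
#' @param negate count negatives instead of positives.
#' @return list with `n_positive` and `n_total`.
#' @export
marker_counts <- function(table, marker, group = c("cowden", "non_cowden", "all"),
                          negate = FALSE) {
  group <- match.arg(group)
  rows <- switch(group,
                 cowden = tolower(table$cowden_disease) == "yes",
                 non_cowden = tolower(table$cowden_disease) == "no",
                 all = rep(TRUE, nrow(table)))
  if (!any(rows)) stop("empty group: ", group)
  sub <- table[rows, , drop = FALSE]
  val <- sub[[marker]]
  pos <- if (marker == "ERBB2") {
    vapply(val, function(v) positivity("ERBB2", herceptest = v), logical(1L))
  } else {
    sc <- suppressWarnings(as.integer(val))
    vapply(sc, function(s) positivity(marker, score = s), logical(1L))
  }
  keep <- !is.na(pos)
  if (negate) pos <- !pos
  list(n_positive = sum(pos[keep]), n_total = sum(keep))
}

#' Chi-square / Fisher test on a contingency table
#'
#' Pearson chi-square test of independence (no continuity correction); for
#' 2 x 2 tables whose smallest expected count is at most 5 the two-sided
#' Fisher exact test (minimum-likelihood convention) is substituted, so the
#' classical boundary case falls to the exact test. Sparse r x c tables
#' keep the chi-square with a warning.
#'
#' @param counts matrix of non-negative integer counts.
#' @return list with `statistic` (`NA` for Fisher), `p_value`, `test_used`
#'   and the input `table`.
#' @export
contingency_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("contingency table has a zero margin")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (all(dim(counts) == c(2L, 2L)) && any(expected <= 5)) {
    ft <- stats::fisher.test(counts)
    return(list(statistic = NA_real_, p_value = ft$p.value,
                test_used = "fisher", table = counts))
  }
  if (any(expected < 5))
    warning("sparse r x c table: chi-square approximation may be poor")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       test_used = "chi_square", table = counts)
}

#' Positive-proportion comparison between two groups for one marker
#'
#' Convenience wrapper building the 2 x 2 table (positive/negative by
#' group) from marker counts and running [contingency_test()].
#'
#' @param n_pos_a,n_a positives and evaluable totals in group A.
#' @param n_pos_b,n_b positives and evaluable totals in group B.
#' @return As [contingency_test()].
#' @export
proportion_test <- function(n_pos_a, n_a, n_pos_b, n_b) {
  m <- matrix(c(n_pos_a, n_a - n_pos_a, n_pos_b, n_b - n_pos_b),
              nrow = 2L, byrow = TRUE,
              dimnames = list(group = c("A", "B"),
                              status = c("positive", "negative")))
  contingency_test(m)
}
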