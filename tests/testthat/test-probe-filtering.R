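make_matrix <- function(rows) {
  X <- do.call(rbind, rows)
  rownames(X) <- names(rows)
  colnames(X) <- sprintf("S%02d", seq_len(ncol(X)))
  X
}

test_that("intensity filter keeps expressed non-control probes", {
  X <- make_matrix(list(bright = rep(12, 10),
                        `AFFX-ctrl` = rep(12, 10),
                        dim = 1:10))
  ann <- data.frame(probe_id = rownames(X), gene_symbol = "", unigene_id = "",
                    entrez_id = "", is_control = c(FALSE, TRUE, FALSE))
  kept <- intensity_filter(X, ann)
  expect_true("bright" %in% kept)
  expect_false("AFFX-ctrl" %in% kept)      # control probes removed regardless
  # 90th percentile of 1..10 interpolates to 9.1 < 10
  expect_false("dim" %in% kept)
  expect_error(intensity_filter(X[0, , drop = FALSE], ann), "empty|probe ids")
})

test_that("variance test matches the chi-square formulation", {
  set.seed(4)
  x <- rnorm(11)
  vt <- variance_test(x, varmed = var(x))
  expect_equal(vt$statistic, 10)            # (n-1) * Var/Var

  # n = 4, variance 9 against varmed 1: statistic 27, upper-tail chi-square(3)
  y <- c(0, 3, 6, 9) * sqrt(9 / var(c(0, 3, 6, 9)))
  vt <- variance_test(y, varmed = 1)
  expect_equal(vt$statistic, 27)
  expect_equal(vt$p_value, 5.88735558358e-06, tolerance = 1e-9)

  vt <- variance_test(rep(5, 8), varmed = 2)
  expect_equal(vt$statistic, 0)
  expect_equal(vt$p_value, 1)

  expect_error(variance_test(x, varmed = 0), "varmed")
  expect_error(variance_test(1, varmed = 1), "n >= 2")
})

test_that("robust CV trims exactly one minimum and one maximum", {
  expect_equal(robust_cv(c(1, 2, 3, 4, 10)), 1 / 3)   # sd(2,3,4)/mean(2,3,4)
  expect_equal(robust_cv(c(5, 5, 5, 5)), 0)
  expect_equal(robust_cv(c(0, 7, 7, 7, 100)), 0)      # constant after trim
  expect_error(robust_cv(c(1, 2, 3)), "n >= 4")
  expect_true(is.na(robust_cv(c(-2, -1, 0, 1, 2))))   # trimmed mean zero
})

test_that("clustering-probe selection enforces the full criterion chain", {
  set.seed(7)
  n <- 40
  X <- matrix(rnorm(1000 * n, 11, 0.3), nrow = 1000,
              dimnames = list(sprintf("P%04d", 1:1000), sprintf("S%02d", 1:n)))
  sel <- select_clustering_probes(X, apply_intensity = FALSE)
  rep <- sel$report
  expect_true(rep$n_after_intensity <= rep$n_input)
  expect_true(rep$n_after_rcv <= rep$n_after_variance)
  expect_identical(length(sel$probes), rep$n_after_rcv)
  # selection is a subset of the variance-test screen
  pp <- rep$per_probe
  expect_true(all(pp$p_value[pp$kept] < 0.01))
  # a probe failing only the rCV window is excluded with the reason recorded
  failed_rcv <- pp$pass_variance & !pp$pass_rcv
  if (any(failed_rcv)) expect_false(any(pp$kept[failed_rcv]))
  # null data: roughly 1% pass the variance screen
  expect_lt(rep$n_after_variance / rep$n_after_intensity, 0.05)
})

test_that("selection recovers planted high-variance probes", {
  set.seed(8)
  n <- 74
  null <- matrix(rnorm(5000 * n, 11, 0.5), nrow = 5000)
  planted <- matrix(rnorm(50 * n, 11, 0.5), nrow = 50)
  planted[, 1:15] <- planted[, 1:15] + 2        # strong class-like offset
  X <- rbind(null, planted)
  dimnames(X) <- list(c(sprintf("N%04d", 1:5000), sprintf("DE%02d", 1:50)),
                      sprintf("S%02d", 1:n))
  sel <- select_clustering_probes(X, apply_intensity = FALSE)
  expect_gte(sum(grepl("^DE", sel$probes)), 45)
})

test_that("selection is invariant to probe and sample order", {
  set.seed(9)
  X <- matrix(rnorm(400 * 20, 11, 0.5), nrow = 400,
              dimnames = list(sprintf("P%03d", 1:400), sprintf("S%02d", 1:20)))
  X[1:10, 1:6] <- X[1:10, 1:6] + 3
  a <- select_clustering_probes(X, apply_intensity = FALSE)
  b <- select_clustering_probes(X[sample(nrow(X)), sample(ncol(X))],
                                apply_intensity = FALSE)
  expect_setequal(a$probes, b$probes)
})
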