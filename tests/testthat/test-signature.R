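test_that("Welch t matches the closed form and the stats oracle", {
  w <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3.67423461417, tolerance = 1e-10)
  expect_equal(w$df, 4)
  expect_equal(w$p, 0.0213116411288, tolerance = 1e-10)
  tt <- stats::t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, unname(tt$statistic))
  expect_equal(w$p, tt$p.value)

  same <- welch_t(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  sw <- welch_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$t, -w$t)
  expect_equal(sw$p, w$p)
  expect_error(welch_t(1, c(1, 2)), "two values")
})

test_that("vectorised Welch agrees with per-probe t.test", {
  set.seed(31)
  X <- matrix(rnorm(50 * 12), nrow = 50,
              dimnames = list(sprintf("P%02d", 1:50), sprintf("s%02d", 1:12)))
  st <- apocrine:::.row_welch_t(X, 1:5, 6:12)
  for (i in c(1, 17, 50)) {
    tt <- stats::t.test(X[i, 1:5], X[i, 6:12])
    expect_equal(st$t_statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(st$welch_df[i], unname(tt$parameter), tolerance = 1e-10)
    expect_equal(st$p_value[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("local FDR handles the degenerate and null regimes", {
  res <- local_fdr(rep(0.5, 500))
  expect_true(res$degenerate)
  expect_equal(res$lfdr, rep(1, 500))

  set.seed(32)
  res <- local_fdr(runif(5000))
  expect_gte(res$pi0, 0.9)
  expect_gte(stats::median(res$lfdr), 0.9)

  # out-of-range p-values are clamped, not propagated
  res <- local_fdr(c(0, runif(499), 1))
  expect_identical(res$n_clamped, 2L)
  expect_true(all(res$lfdr >= 0 & res$lfdr <= 1))
})

test_that("local FDR recovers the null proportion of a planted mixture", {
  set.seed(33)
  p <- c(runif(4000), pnorm(rnorm(1000, -2, 1)))
  res <- local_fdr(p)
  expect_lt(abs(res$pi0 - 0.8), 0.1)
  # non-null p-values get markedly lower lfdr than nulls on average
  expect_lt(mean(res$lfdr[4001:5000]), mean(res$lfdr[1:4000]))
})

test_that("random forest ranks a perfectly separating probe first", {
  set.seed(34)
  n <- 30
  X <- matrix(rnorm(51 * n), nrow = 51,
              dimnames = list(c("SEP", sprintf("N%02d", 1:50)),
                              sprintf("s%02d", 1:n)))
  grp <- rep(c("a", "b"), each = n / 2)
  X["SEP", grp == "a"] <- X["SEP", grp == "a"] + 5
  rk <- forest_select(X, grp, rownames(X), n_keep = 10, n_trees = 300,
                      seed = 99)
  expect_identical(rk$probe_id[1], "SEP")
  rk2 <- forest_select(X, grp, rownames(X), n_keep = 10, n_trees = 300,
                       seed = 99)
  expect_identical(rk, rk2)                       # same seed, same ranking
  expect_warning(forest_select(X, grp, rownames(X)[1:5], n_keep = 10,
                               n_trees = 50, seed = 1), "exceeds")
})

test_that("signature derivation screens, selects and orients correctly", {
  g <- generate_expression(n_samples = 40, n_probes = 2000, n_apocrine = 6,
                           n_cowden = 3, apocrine_block = 40,
                           apocrine_down = 20, seed = 35)
  grp <- ifelse(g$truth$classes == "apocrine", "apocrine", "other")
  sig <- suppressWarnings(derive_signature(g$expression, grp,
                                           annotation = g$annotation,
                                           n_keep = 60, n_trees = 300,
                                           seed = 7))
  expect_lte(length(sig$selected), 60L)
  st <- sig$stats
  # selection never escapes the screen
  expect_true(all(st$p_value[st$selected] < 0.01))
  # directions agree with group-mean differences
  apo <- which(grp == "apocrine"); oth <- which(grp == "other")
  for (pid in sample(sig$selected, 10)) {
    d <- mean(g$expression[pid, apo]) - mean(g$expression[pid, oth])
    expect_identical(st$direction[st$probe_id == pid],
                     if (d >= 0) "up" else "down")
  }
  # swapping the groups flips directions but keeps the same probes
  sig2 <- suppressWarnings(derive_signature(
    g$expression, ifelse(grp == "apocrine", "zz_other", "apocrine"),
    annotation = g$annotation, n_keep = 60, n_trees = 300, seed = 7))
  expect_setequal(sig$selected, sig2$selected)
  m <- match(sig$stats$probe_id, sig2$stats$probe_id)
  expect_true(all(sig$stats$direction != sig2$stats$direction[m]))
})

test_that("a p threshold of 1 screens nothing out", {
  g <- generate_expression(n_samples = 24, n_probes = 400, n_apocrine = 6,
                           n_cowden = 3, apocrine_block = 20,
                           class_block = 10, seed = 36)
  grp <- ifelse(g$truth$classes == "apocrine", "apocrine", "other")
  sig <- suppressWarnings(derive_signature(g$expression, grp, p_thresh = 1,
                                           n_keep = 50, n_trees = 200,
                                           seed = 2))
  expect_identical(sig$screen_size, nrow(g$expression))
  expect_identical(length(sig$selected), 50L)
})
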