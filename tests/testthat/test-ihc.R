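test_that("the 0/1/2 score follows the percent bands", {
  expect_identical(score_from_percent(0), 0L)
  expect_identical(score_from_percent(5), 1L)
  expect_identical(score_from_percent(10), 1L)
  expect_identical(score_from_percent(10.5), 2L)
  expect_identical(score_from_percent(50), 2L)
  expect_identical(score_from_percent(100), 2L)
  expect_error(score_from_percent(101), "0, 100")
})

test_that("positivity rules are marker-specific", {
  expect_false(positivity("ER", score = 1))       # hormone receptors need 2
  expect_true(positivity("ER", score = 2))
  expect_true(positivity("GGT1", score = 1))      # 1% staining threshold
  expect_false(positivity("GGT1", score = 0))
  expect_true(positivity("PTEN", score = 1))
  expect_true(positivity("ERBB2", herceptest = "+++"))
  expect_false(positivity("ERBB2", herceptest = "++"))
  expect_true(is.na(positivity("ERBB2", herceptest = "nd")))
  expect_error(positivity("KI67", score = 2), "unknown marker")
})

test_that("the shipped summary-table fixture reproduces the printed counts", {
  tab <- read_ihc_table(table2_path())
  expect_identical(nrow(tab), 17L)
  ggt1 <- marker_counts(tab, "GGT1", "cowden")
  expect_identical(c(ggt1$n_positive, ggt1$n_total), c(12L, 15L))
  gcdfp <- marker_counts(tab, "GCDFP15", "cowden")
  expect_identical(c(gcdfp$n_positive, gcdfp$n_total), c(8L, 15L))
  pten_neg <- marker_counts(tab, "PTEN", "cowden", negate = TRUE)
  expect_identical(c(pten_neg$n_positive, pten_neg$n_total), c(13L, 15L))
  # AR positive throughout, and the 'nd' ERBB2 reading drops a denominator
  ar <- marker_counts(tab, "AR", "cowden")
  expect_identical(ar$n_positive, 15L)
  erbb2 <- marker_counts(tab, "ERBB2", "cowden")
  expect_identical(erbb2$n_total, 14L)
})

test_that("the contingency test switches to Fisher only when warranted", {
  res <- contingency_test(matrix(c(10, 0, 0, 10), 2))
  expect_identical(res$test_used, "fisher")
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  res <- contingency_test(matrix(c(5, 5, 5, 5), 2))
  expect_identical(res$test_used, "fisher")   # boundary expected count of 5
  expect_equal(res$p_value, 1)

  res <- contingency_test(matrix(c(50, 30, 30, 50), 2))
  expect_identical(res$test_used, "chi_square")

  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero margin")
  expect_error(contingency_test(matrix(c(1.5, 2, 3, 4), 2)), "integers")
  expect_warning(contingency_test(matrix(c(1, 2, 0, 3, 1, 2), 2)), "sparse")
})

test_that("Fisher p equals full enumeration for random small tables", {
  set.seed(71)
  checked <- 0
  while (checked < 60) {
    N <- sample(8:100, 1)
    m <- sample(1:(N - 1), 1)
    k <- sample(1:(N - 1), 1)
    a <- sample(max(0, k - (N - m)):min(k, m), 1)
    tab <- matrix(c(a, m - a, k - a, N - m - k + a), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ft <- stats::fisher.test(tab)$p.value
    expect_equal(ft, fisher_enum(tab), tolerance = 1e-9)
    checked <- checked + 1
  }
  # the grouped-proportion wrapper routes through the same machinery
  res <- proportion_test(12, 15, 1, 69)
  expect_identical(res$test_used, "fisher")
  expect_equal(res$p_value,
               fisher_enum(matrix(c(12, 3, 1, 68), 2, byrow = TRUE)),
               tolerance = 1e-12)
})

test_that("synthetic IHC tables honour the positivity probabilities", {
  g <- generate_ihc(group_sizes = c(cowden = 10, apocrine = 5, control = 20),
                    positivity_probs = rbind(cowden = c(GGT1 = 1),
                                             apocrine = c(GGT1 = 1),
                                             control = c(GGT1 = 0)),
                    seed = 72)
  counts_c <- marker_counts(g$table, "GGT1", "cowden")
  expect_identical(counts_c$n_positive, 10L)
  counts_n <- marker_counts(g$table, "GGT1", "non_cowden")
  expect_identical(counts_n$n_positive, 5L)   # the apocrine group
  # detail rows are consistent with the wide scores
  d <- g$detail[g$detail$marker == "GGT1", ]
  expect_identical(as.integer(g$table$GGT1), d$score)
  expect_identical(d$score, score_from_percent(d$percent_positive))
})

test_that("group separation is detectable at cohort-like sizes", {
  hits <- vapply(1:10, function(s) {
    g <- generate_ihc(group_sizes = c(cowden = 15, apocrine = 0, control = 69),
                      positivity_probs = rbind(cowden = c(GGT1 = 0.8),
                                               apocrine = c(GGT1 = 1),
                                               control = c(GGT1 = 0.01)),
                      seed = 100 + s)
    a <- marker_counts(g$table, "GGT1", "cowden")
    b <- marker_counts(g$table, "GGT1", "non_cowden")
    proportion_test(a$n_positive, a$n_total, b$n_positive, b$n_total)$p_value
  }, numeric(1))
  expect_gte(mean(hits < 1e-6), 0.9)
})
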