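test_that("clone aggregation applies the QC filters in order", {
  # four concordant high-snr spots
  expect_equal(aggregate_clone(cy3 = rep(150, 4), cy5 = rep(100, 4),
                               snr = rep(10, 4)), 1.5)
  # replicate log2-ratio SD above 0.1 invalidates the clone
  cy5 <- rep(100, 4)
  cy3 <- 100 * 2^c(-0.4, 0, 0.2, 0.3)      # log2 SD ~ 0.3
  expect_true(is.na(aggregate_clone(cy3, cy5, snr = rep(10, 4))))
  # a low-snr spot is dropped before the median (replicate-SD cap relaxed
  # so the snr filter alone is exercised)
  expect_equal(aggregate_clone(cy3 = c(100, 100, 200, 120),
                               cy5 = rep(100, 4),
                               snr = c(10, 10, 1, 10), sd_max = 0.5), 1.0)
  # nothing survives -> missing; non-positive intensities invalidate spots
  expect_true(is.na(aggregate_clone(100, 100, snr = 1)))
  expect_true(is.na(aggregate_clone(c(-5, 100), c(100, 0), snr = c(10, 10))))
})

test_that("status thresholds are strict and on the linear ratio scale", {
  expect_identical(call_status(c(1.0, 1.5, 0.5, 2.5, 1.2, 0.8, 2.0, NA)),
                   c("normal", "gain", "loss", "amplicon", "normal",
                     "normal", "gain", "missing"))
  # literal log2 reading for comparison
  expect_identical(call_status(2^c(1.5, 0.5), literal_log = TRUE),
                   c("gain", "loss"))
})

test_that("sparse-clone exclusion uses a strict majority rule", {
  r <- rbind(a = c(1, 1, NA, NA, NA),   # missing in 3/5 -> removed
             b = c(1, 1, 1, 1, 1),      # complete -> kept
             c = c(1, NA, 1, NA, 1))    # missing in 2/5 -> kept
  colnames(r) <- sprintf("t%d", 1:5)
  expect_identical(exclude_sparse_clones(r), c("b", "c"))
  r2 <- rbind(d = c(1, NA, 1, NA))      # exactly 50% -> kept
  colnames(r2) <- sprintf("t%d", 1:4)
  expect_identical(exclude_sparse_clones(r2), "d")
})

test_that("perturbation rate is the unweighted mean of per-arm fractions", {
  clones <- data.frame(clone_id = sprintf("c%d", 1:8),
                       chromosome = rep(c("1", "2"), each = 4),
                       position = rep(c(1e6, 2e6, 3e6, 4e6), 2))
  cmap <- data.frame(chromosome = c("1", "2"), centromere = c(5e6, 5e6),
                     length = c(1e7, 1e7))
  st <- c("gain", "loss", "normal", "normal", rep("normal", 4))
  res <- perturbation_rate(st, clones, cmap)
  expect_equal(res$rate, mean(c(0.5, 0)))
  expect_identical(res$per_arm$n_informative, c(4L, 4L))

  expect_equal(perturbation_rate(rep("normal", 8), clones, cmap)$rate, 0)
  expect_equal(perturbation_rate(rep("gain", 8), clones, cmap)$rate, 1)
  # arm assignment: positions at or past the centromere go to q
  clones_q <- transform(clones, position = position + 5e6 - 1e6)
  res_q <- perturbation_rate(st, clones_q, cmap)
  expect_true(any(res_q$per_arm$arm == "q"))
  expect_error(perturbation_rate(st, transform(clones, chromosome = "99"),
                                 cmap), "absent")
})

test_that("noise-free synthetic profiles are recovered exactly", {
  g <- generate_acgh(n_clones = 600, noise_sd = 0, low_snr_frac = 0,
                     seed = 51)
  ratios <- aggregate_ratios(g$experiment)
  expect_false(any(is.na(ratios)))
  calls <- apply(ratios, 2, call_status)
  expect_identical(calls, g$truth$true_status)
  for (tid in colnames(calls)) {
    pr <- perturbation_rate(calls[, tid], g$experiment$clones, g$centromeres)
    expect_equal(pr$rate, unname(g$truth$rates[tid]), tolerance = 1e-12)
  }
})

test_that("rate recovery is robust to log-normal spot noise", {
  errs <- vapply(1:5, function(s) {
    g <- generate_acgh(n_clones = 500, noise_sd = 0.05, seed = 60 + s)
    ratios <- aggregate_ratios(g$experiment)
    keep <- exclude_sparse_clones(ratios)
    ratios <- ratios[keep, , drop = FALSE]
    clones <- g$experiment$clones[match(keep, g$experiment$clones$clone_id), ]
    max(vapply(colnames(ratios), function(tid) {
      rec <- perturbation_rate(call_status(ratios[, tid]), clones,
                               g$centromeres)$rate
      abs(rec - g$truth$rates[tid])
    }, numeric(1)))
  }, numeric(1))
  expect_lt(max(errs), 0.02)
})

test_that("rate is invariant to clone order", {
  g <- generate_acgh(n_clones = 400, seed = 52)
  ratios <- aggregate_ratios(g$experiment)
  clones <- g$experiment$clones
  st <- call_status(ratios[, 1])
  base <- perturbation_rate(st, clones, g$centromeres)$rate
  perm <- sample(nrow(clones))
  expect_equal(perturbation_rate(st[perm], clones[perm, ], g$centromeres)$rate,
               base)
})

test_that("genome plots render without error", {
  g <- generate_acgh(n_clones = 300, seed = 53)
  ratios <- aggregate_ratios(g$experiment)
  f <- withr::local_tempfile(fileext = ".png")
  expect_no_error(genome_plot(call_status(ratios[, 1]), g$experiment$clones,
                              g$centromeres, file = f))
  expect_true(file.exists(f))
})
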