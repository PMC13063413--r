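test_that("chemical_stddev is the N-1 sample stddev over valid sites", {
  expect_equal(chemical_stddev(c(-1, 0, 1)), 1.0)
  expect_equal(chemical_stddev(rep(0.3, 5)), 0.0)
  expect_equal(chemical_stddev(c(0.1, 0.3, 0.5, 0.9)), sqrt(0.35 / 3))
  expect_equal(chemical_stddev(c(1, NA, 2, NA, 3)), 1.0)
  expect_error(chemical_stddev(c(1, 2)), class = "rembench_insufficient_data_error")
})

test_that("benchmark_residuals realizes the benchmarking transform", {
  # chemical = benchmark + 0.7 everywhere: perfect benchmarking
  m <- matrix_from_rows(list(A = c(0, 1, 2), B = c(0.7, 1.7, 2.7)))
  br <- benchmark_residuals(m, "B", "A")
  expect_equal(unname(br$residuals), c(0, 0, 0))
  expect_equal(br$n_gap_filled, 0L)

  # constant benchmark: residuals are the chemical's own centered residuals
  m2 <- matrix_from_rows(list(A = c(0, 1, 2), K = c(5, 5, 5)))
  br2 <- benchmark_residuals(m2, "A", "K")
  expect_equal(unname(br2$residuals), c(-1, 0, 1))

  # gap rule: benchmark missing at s3, raw residual 2 - 1 = 1 fills in
  m3 <- matrix_from_rows(list(A = c(0, 1, 2), B = c(0, 1, NA)))
  br3 <- benchmark_residuals(m3, "A", "B")
  expect_equal(br3$residuals, c(s1 = 0, s2 = 0, s3 = 1))
  expect_equal(br3$n_gap_filled, 1L)
  expect_equal(br3$n_sites, 3L)

  expect_error(benchmark_residuals(m, "A", "A"),
               class = "rembench_usage_error")
  m4 <- matrix_from_rows(list(A = c(0, 1, 2, NA), B = c(NA, NA, NA, 1)))
  expect_error(benchmark_residuals(m4, "A", "B"),
               class = "rembench_insufficient_overlap_error")
})

test_that("benchmarked residuals over shared sites are mean-centered", {
  withr::local_seed(17)
  for (i in 1:20) {
    m <- random_rate_matrix(4, 10, p_missing = 0.25)
    for (pair in list(c("C01", "C02"), c("C03", "C04"))) {
      br <- tryCatch(benchmark_residuals(m, pair[1], pair[2]),
                     rembench_error = function(e) NULL)
      if (is.null(br)) next
      shared <- !is.na(m[pair[2], names(br$residuals)])
      if (any(shared)) {
        expect_lt(abs(sum(br$residuals[shared])), 1e-9)
      }
    }
  }
})

test_that("rem reproduces hand-computed cases and its exact limits", {
  # perfect benchmark: stddev_after 0, REM = stddev_before, exactly
  # (integer base, dyadic offset: the arithmetic is exact in doubles)
  m <- matrix_from_rows(list(A = c(0, 1, 2, 5), B = c(0.5, 1.5, 2.5, 5.5)))
  r <- rem(m, "B", "A")
  expect_identical(r$stddev_after, 0)
  expect_identical(r$rem, r$stddev_before)

  # constant benchmark: REM exactly 0
  m2 <- matrix_from_rows(list(A = c(0, 1, 2, 5), K = c(3, 3, 3, 3)))
  r2 <- rem(m2, "A", "K")
  expect_identical(r2$rem, 0)

  # worked example: benchmarked series (0, 0, 2)
  m3 <- matrix_from_rows(list(A = c(0, 1, 2), B = c(0, 1, 0)))
  r3 <- rem(m3, "A", "B")
  expect_equal(r3$stddev_before, 1.0)
  expect_equal(r3$stddev_after, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(r3$rem, 1 - 2 / sqrt(3), tolerance = 1e-12)
})

test_that("rem is invariant to adding a constant to any row", {
  withr::local_seed(23)
  m <- random_rate_matrix(3, 12, p_missing = 0.2)
  r0 <- rem(m, "C01", "C02")
  shifted <- unclass(m)
  shifted["C01", ] <- shifted["C01", ] + 3.1
  shifted["C02", ] <- shifted["C02", ] - 1.7
  r1 <- rem(rate_matrix(shifted), "C01", "C02")
  expect_equal(r1$rem, r0$rem, tolerance = 1e-12)
  expect_equal(r1$stddev_before, r0$stddev_before, tolerance = 1e-12)
})

test_that("median_rem aggregates candidate REMs and counts skips", {
  withr::local_seed(31)
  m <- random_rate_matrix(6, 10, p_missing = 0.1)
  mr <- median_rem(m, "C01")
  manual <- vapply(sprintf("C%02d", 2:6),
                   function(ch) rem(m, ch, "C01")$rem, numeric(1))
  expect_equal(as.numeric(mr), stats::median(manual), tolerance = 1e-12)
  expect_equal(attr(mr, "n_evaluated"), 5L)

  # single candidate: the median is that candidate's REM
  mr1 <- median_rem(m, "C01", candidates = "C02")
  expect_equal(as.numeric(mr1), rem(m, "C02", "C01")$rem)

  # a candidate with too few valid sites is skipped, not propagated
  m2 <- unclass(m)
  m2["C02", 3:10] <- NA
  mr2 <- median_rem(rate_matrix(m2), "C01")
  expect_equal(attr(mr2, "n_skipped"), 1L)
  expect_equal(attr(mr2, "n_evaluated"), 4L)
})

test_that("select_benchmark picks the largest median REM deterministically", {
  # two exactly parallel chemicals: symmetric tie, lexicographic winner
  m <- matrix_from_rows(list(B = c(0.5, 1.5, 0.2), A = c(0, 1, -0.3)))
  sel <- select_benchmark(m)
  expect_equal(sel$benchmark_id, "A")
  expect_equal(sel$rem_table$median_rem[1], sel$rem_table$median_rem[2],
               tolerance = 1e-12)

  # a parallel pair plus an independent-noise chemical: winner in the pair
  withr::local_seed(41)
  base <- stats::rnorm(12)
  m2 <- matrix_from_rows(list(A = base, B = base + 0.4,
                              C = stats::rnorm(12)))
  sel2 <- select_benchmark(m2)
  expect_true(sel2$benchmark_id %in% c("A", "B"))

  expect_error(select_benchmark(m, pool = "A"),
               class = "rembench_usage_error")
})

test_that("run_ubm benchmarks all chemicals against one selection", {
  # mutually parallel chemicals: full reduction for everyone
  withr::local_seed(47)
  base <- stats::rnorm(10)
  m <- matrix_from_rows(list(A = base, B = base + 1, C = base - 0.5,
                             D = base + 0.2))
  res <- run_ubm(m)
  expect_equal(res$mode, "UBM")
  expect_equal(nrow(res$per_chemical), 3)
  expect_equal(res$summary$fraction_rem_positive, 1.0)
  expect_equal(res$per_chemical$stddev_after, rep(0, 3), tolerance = 1e-12)
  expect_equal(res$summary$median_rem,
               stats::median(res$per_chemical$stddev_before),
               tolerance = 1e-12)

  # two chemicals: exactly one benchmarked entry
  m2 <- matrix_from_rows(list(A = base, B = base + stats::rnorm(10, 0, 0.1)))
  expect_equal(nrow(run_ubm(m2)$per_chemical), 1)
})

test_that("independent equal-variance chemicals give negative median REM", {
  # large-N expectation: stddev_after -> sqrt(2) * sigma, so median REM
  # approaches (1 - sqrt(2)) * sigma
  withr::local_seed(53)
  sigma <- 0.3
  meds <- vapply(1:40, function(i) {
    m <- rate_matrix(matrix(stats::rnorm(40 * 38, 0, sigma), 40, 38,
                            dimnames = list(sprintf("C%02d", 1:40),
                                            sprintf("S%02d", 1:38))))
    as.numeric(median_rem(m, "C01"))
  }, numeric(1))
  expect_true(all(meds < 0))
  se <- stats::sd(meds) / sqrt(length(meds))
  expect_lt(abs(mean(meds) - (1 - sqrt(2)) * sigma), 3 * se + 0.01)
})

test_that("run_gbm reduces to run_ubm for a single group", {
  withr::local_seed(59)
  m <- random_rate_matrix(5, 10, p_missing = 0.1)
  one_group <- group_assignment(stats::setNames(rep(1, 5), rownames(m)))
  gbm <- run_gbm(m, one_group)
  ubm <- run_ubm(m)
  expect_equal(gbm$per_chemical$rem, ubm$per_chemical$rem, tolerance = 1e-12)
  expect_equal(unname(gbm$assignments[names(ubm$assignments)]),
               unname(ubm$assignments))
})

test_that("run_gbm benchmarks within groups and pools the summary", {
  withr::local_seed(61)
  b1 <- stats::rnorm(10); b2 <- stats::rnorm(10)
  m <- matrix_from_rows(list(A = b1, B = b1 + 0.8,
                             C = b2, D = b2 - 0.3))
  grouping <- group_assignment(c(A = 1, B = 1, C = 2, D = 2))
  res <- run_gbm(m, grouping)
  expect_equal(res$mode, "GBM")
  expect_equal(nrow(res$per_chemical), 2) # one benchmark per group excluded
  expect_equal(res$per_chemical$stddev_after, rep(0, 2), tolerance = 1e-12)
  expect_gt(res$summary$median_rem, 0)
  expect_equal(nrow(res$summary$per_group), 2)

  singleton <- group_assignment(c(A = 1, B = 1, C = 2, D = 3))
  expect_error(run_gbm(m, singleton), "3", class = "rembench_config_error")
  expect_error(run_gbm(m, group_assignment(c(A = 1, B = 1, C = 2))),
               "D", class = "rembench_config_error")
})

test_that("TOC normalization equals benchmarking against a TOC pseudo-chemical", {
  withr::local_seed(67)
  m <- random_rate_matrix(4, 12, p_missing = 0.2)
  toc <- stats::setNames(10^stats::runif(12, -0.5, 1), colnames(m))
  res <- run_toc(m, toc)
  # dual route: augment the matrix with log10 TOC as a pseudo-chemical row
  aug <- rate_matrix(rbind(unclass(m), TOCROW = log10(toc)))
  for (i in seq_len(nrow(res$per_chemical))) {
    chem <- res$per_chemical$chemical_id[i]
    r <- rem(aug, chem, "TOCROW")
    expect_equal(res$per_chemical$rem[i], r$rem, tolerance = 1e-12)
    expect_equal(res$per_chemical$stddev_after[i], r$stddev_after,
                 tolerance = 1e-12)
  }
  # constant TOC changes nothing
  res_const <- run_toc(m, stats::setNames(rep(2, 12), colnames(m)))
  expect_equal(res_const$per_chemical$rem, rep(0, 4), tolerance = 1e-12)
})

test_that("summaries report medians, fractions and fold factors", {
  fake <- list(per_chemical = data.frame(
    chemical_id = c("A", "B", "C"), group = 1L, benchmark_id = "Z",
    n_sites = 5L, n_gap_filled = 0L, stddev_before = c(0.5, 0.4, 0.6),
    stddev_after = c(0.4, 0.5, 0.3), rem = c(0.1, -0.1, 0.3)),
    n_skipped = 0L)
  s <- summarize_benchmark(fake)
  expect_equal(s$median_rem, 0.1)
  expect_equal(s$fraction_rem_positive, 2 / 3)
  expect_equal(s$median_fold_factor, 10^0.1)

  zero <- fake
  zero$per_chemical$rem <- rep(0, 3)
  s0 <- summarize_benchmark(zero)
  expect_equal(s0$fraction_rem_positive, 0)
  expect_equal(s0$median_rem, 0)

  one <- fake
  one$per_chemical <- one$per_chemical[1, , drop = FALSE]
  expect_equal(summarize_benchmark(one)$median_rem, 0.1)
})

test_that("fold_factor converts log10 quantities to multiplicative spread", {
  expect_equal(fold_factor(0), 1)
  expect_equal(fold_factor(1), 10)
  expect_equal(fold_factor(c(0.3, -0.3)), c(10^0.3, 10^-0.3))
})

test_that("REM self-consistency holds in every mode", {
  withr::local_seed(71)
  m <- random_rate_matrix(8, 12, p_missing = 0.15)
  for (res in list(run_ubm(m),
                   run_gbm(m, group_assignment(stats::setNames(
                     rep(1:2, each = 4), rownames(m)))),
                   run_toc(m, stats::setNames(rep(2, 12), colnames(m))))) {
    expect_equal(res$per_chemical$rem,
                 res$per_chemical$stddev_before - res$per_chemical$stddev_after,
                 tolerance = 1e-12)
    expect_true(all(res$per_chemical$rem <=
                      res$per_chemical$stddev_before + 1e-12))
    # benchmarks never appear among their own entries
    expect_false(any(res$per_chemical$chemical_id ==
                       res$per_chemical$benchmark_id))
  }
})
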