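loci3 <- c("L1", "L2", "L3")

test_that("detection rates count baseline and ever-detected panel loci", {
  maf <- matrix(c(0.1, 0.2, 0.05,
                  0.1, 0.2, 0.05), nrow = 3,
                dimnames = list(loci3, NULL))
  s <- series_from_matrix(maf, c(0, 28))
  expect_equal(detection_rates(s, loci3),
               c(baseline_rate = 1, ever_rate = 1))

  none <- series_from_matrix(maf * 0, c(0, 28))
  expect_equal(detection_rates(none, loci3),
               c(baseline_rate = 0, ever_rate = 0))

  # random detection matrix vs column-wise any/first-row oracle
  set.seed(44)
  for (i in 1:10) {
    m <- matrix(sample(c(0, 0.004, 0.05), 12, replace = TRUE), nrow = 3,
                dimnames = list(loci3, NULL))
    s <- series_from_matrix(m, c(0, 28, 56, 84))
    det <- m * 1000 >= 3
    got <- detection_rates(s, loci3)
    expect_equal(got[["baseline_rate"]], mean(det[, 1]))
    expect_equal(got[["ever_rate"]], mean(apply(det, 1, any)))
    expect_gte(got[["ever_rate"]], got[["baseline_rate"]])
  }

  # no baseline draw: baseline undefined, ever still computed
  s <- series_from_matrix(maf, c(14, 28))
  dr <- detection_rates(s, loci3)
  expect_true(is.na(dr[["baseline_rate"]]))
  expect_equal(dr[["ever_rate"]], 1)
})

test_that("mean MAF zero-imputes undetected panel loci", {
  s <- series_from_matrix(matrix(c(0.10, 0.20, 0), nrow = 3,
                                 dimnames = list(loci3, NULL)), 0)
  expect_equal(mean_maf(s, 0, loci3), 0.10)
  expect_equal(mean_maf(s, 0, loci3, detected_only = TRUE), 0.15)
  all0 <- series_from_matrix(matrix(0, 3, 1, dimnames = list(loci3, NULL)), 0)
  expect_equal(mean_maf(all0, 0, loci3), 0.0)
  expect_error(mean_maf(s, 99, loci3), "no ctDNA sample")

  # brute-force zero-imputation oracle, including a locus missing from
  # the draw
  set.seed(45)
  m <- matrix(runif(3, 0, 0.3), nrow = 3, dimnames = list(loci3, NULL))
  s <- series_from_matrix(m, 0)
  s <- s[-2, ]  # drop one locus from the draw
  maf <- s$alt_reads / s$depth
  maf[s$alt_reads < 3] <- 0
  expect_equal(mean_maf(s, 0, loci3), sum(maf) / 3)
})

test_that("fold-change uses the nearest draw, earlier on ties, and is
           scale-invariant", {
  m <- matrix(c(0.20, 0.20, 0.20, 0.05, 0.05, 0.05), nrow = 3,
              dimnames = list(loci3, NULL))
  s <- series_from_matrix(m, c(0, 56))
  fc <- fold_change(s, loci3, week = 8)
  expect_equal(as.numeric(fc), 0.25)
  expect_equal(attr(fc, "day"), 56)

  same <- series_from_matrix(m[, c(1, 1)], c(0, 56))
  expect_equal(as.numeric(fold_change(same, loci3, week = 8)), 1.0)

  # draws at days 49 and 63 are equidistant from day 56: earlier wins
  s3 <- series_from_matrix(m[, c(1, 2, 2)], c(0, 49, 63))
  expect_equal(attr(fold_change(s3, loci3, week = 8), "day"), 49)

  # scaling every MAF by c > 0 leaves the fold-change unchanged
  s_scaled <- s; s_scaled$alt_reads <- s$alt_reads * 3L
  expect_equal(as.numeric(fold_change(s_scaled, loci3, week = 8)),
               as.numeric(fold_change(s, loci3, week = 8)))

  # zero baseline is flagged, not an error
  z <- series_from_matrix(m * 0, c(0, 56))
  fz <- fold_change(z, loci3, week = 8)
  expect_true(is.na(fz))
  expect_equal(attr(fz, "reason"), "baseline_zero")
  # no draw within the window
  far <- series_from_matrix(m, c(0, 200))
  expect_equal(attr(fold_change(far, loci3, week = 8), "reason"),
               "no_sample")
})

test_that("week-8 response classification is inclusive at 50%", {
  expect_equal(classify_response(0.49), "ctDNA_responder")
  expect_equal(classify_response(0.50), "ctDNA_responder")
  expect_equal(classify_response(1.4), "ctDNA_nonresponder")
  expect_true(is.na(classify_response(NA_real_)))
})

test_that("time to half interpolates linearly between draws", {
  expect_equal(time_to_half(c(0, 28), c(0.20, 0.08)),
               28 * (0.20 - 0.10) / (0.20 - 0.08))  # 23.33
  expect_equal(time_to_half(c(0, 28), c(0.2, 0.1)), 28)
  expect_true(is.na(time_to_half(c(0, 28, 56), c(1, 1.4, 2))))
  # first crossing wins even if the series later re-rises
  expect_equal(time_to_half(c(0, 10, 20, 30), c(1, 0.5, 2, 0.2)), 10)
  expect_error(time_to_half(c(0, 10), c(0, 1)), "positive")
})

test_that("burden concordance pairs draws to scans and matches cor()", {
  days <- c(0, 28, 56, 84)
  mult <- exp(-0.02 * days)
  m <- outer(c(0.1, 0.2, 0.3), mult)
  rownames(m) <- loci3
  s <- series_from_matrix(m, days, depth = 1e5)
  burden <- data.frame(day = c(0, 42, 84), spd_mm2 = 2000 * exp(-0.02 * c(0, 42, 84)))
  conc <- burden_concordance(s, burden, loci3)
  expect_equal(conc$n_pairs, 3)
  # the day-42 scan pairs with the day-28 draw, so the correlation is that
  # of the burden multiplier at slightly offset days — high but below 1
  expect_gt(conc$mean_level_r, 0.95)

  # constant MAF: zero variance, correlation undefined
  flat <- series_from_matrix(matrix(0.1, 3, 4, dimnames = list(loci3, NULL)),
                             days)
  expect_true(is.na(burden_concordance(flat, burden, loci3)$mean_level_r))

  # noisy linear relation: equals the closed-form Pearson on the paired data
  set.seed(46)
  noisy <- m * matrix(runif(12, 0.8, 1.2), 3)
  s2 <- series_from_matrix(noisy, days, depth = 1e5)
  conc2 <- burden_concordance(s2, burden, loci3)
  paired_draws <- c(0, 28, 84)  # nearest draws to scans at 0, 42, 84
  mm <- vapply(paired_draws, mean_maf, numeric(1), series = s2,
               panel_loci = loci3)
  expect_equal(conc2$mean_level_r, cor(mm, burden$spd_mm2))

  # fewer than 3 pairable scans: undefined
  expect_true(is.na(burden_concordance(s, burden[1:2, ], loci3)$mean_level_r))
})

test_that("paired comparison of detection times handles degenerate
           differences", {
  same <- paired_time_comparison(c(10, 20, 30), c(10, 20, 30))
  expect_equal(same$t, 0); expect_equal(same$p, 1)

  const <- paired_time_comparison(c(20, 30, 40), c(70, 80, 90))
  expect_true(const$degenerate)
  expect_equal(const$t, -Inf); expect_equal(const$p, 0)

  # closed-form paired t on the differences
  a <- c(20, 35, 40); b <- c(70, 80, 95)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(3))
  got <- paired_time_comparison(a, b)
  expect_equal(got$t, tstat)
  expect_equal(got$p, 2 * pt(-abs(tstat), 2))
  expect_error(paired_time_comparison(1, 1), ">= 2")
})
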