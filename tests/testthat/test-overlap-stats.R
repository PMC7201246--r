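test_that("overlap percentage is the Jaccard index in percent", {
  expect_equal(overlap_percentage(c("TP53", "EGFR", "TTN"),
                                  c("TP53", "KRAS")), 25.0)
  expect_equal(overlap_percentage(c("A", "B"), c("B", "A")), 100.0)
  expect_equal(overlap_percentage("A", "B"), 0.0)
  expect_error(overlap_percentage(character(), character()), "undefined")

  set.seed(3)
  for (i in 1:20) {
    a <- sample(LETTERS, sample(1:15, 1))
    b <- sample(LETTERS, sample(1:15, 1))
    ov <- overlap_percentage(a, b)
    expect_equal(ov, overlap_percentage(b, a))  # symmetry
    expect_gte(ov, 0); expect_lte(ov, 100)
    expect_equal(overlap_percentage(a, a), 100)
  }
})

test_that("cohort summary matches the brute-force double loop", {
  same <- list(P1 = c("A", "B"), P2 = c("A", "B"), P3 = c("A", "B"))
  s <- cohort_overlap_summary(same)
  expect_equal(unname(s$summary["median"]), 100)
  expect_equal(unname(s$summary["q3"] - s$summary["q1"]), 0)

  disj <- list(P1 = "A", P2 = "B", P3 = "C")
  expect_equal(unname(cohort_overlap_summary(disj)$summary["median"]), 0)

  set.seed(17)
  spectra <- lapply(stats::setNames(1:6, paste0("P", 1:6)), function(i)
    sample(sprintf("G%02d", 1:40), sample(5:25, 1)))
  got <- cohort_overlap_summary(spectra)
  ids <- names(spectra)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    exp_ij <- if (i == j) 100 else
      100 * length(intersect(spectra[[i]], spectra[[j]])) /
        length(unique(c(spectra[[i]], spectra[[j]])))
    expect_equal(got$matrix[i, j], exp_ij)
  }
  expect_equal(got$matrix, t(got$matrix))
  expect_error(cohort_overlap_summary(same[1]), "2 patients")
})

test_that("gene recurrence counts and report percentages", {
  r <- recurrence_stats(list(P1 = c("A", "B"), P2 = c("B", "C"), P3 = "B"))
  expect_equal(r$union_size, 3)
  expect_equal(r$n_shared_ge2, 1)   # only B recurs
  expect_equal(r$pct_ge2, 33.33)
  expect_equal(r$n_shared_gt3, 0)

  # percentages on published-scale counts, half-up to 2 decimals
  expect_equal(shared_gene_percentage(45, 2119), 2.12)
  expect_equal(shared_gene_percentage(19, 2119), 0.90)
  expect_error(shared_gene_percentage(1, 0), "positive")

  # consistency: gt3 <= ge2 <= union
  set.seed(9)
  spectra <- lapply(1:8, function(i) sample(LETTERS, sample(3:20, 1)))
  names(spectra) <- paste0("P", 1:8)
  r <- recurrence_stats(spectra)
  expect_lte(r$n_shared_gt3, r$n_shared_ge2)
  expect_lte(r$n_shared_ge2, r$union_size)
})

test_that("panel-spectrum overlap counts match set intersection", {
  spectra <- list(P1 = c("A", "B", "C"), P2 = c("D", "E"))
  expect_equal(panel_spectrum_overlap(c("X", "Y"), spectra),
               c(P1 = 0L, P2 = 0L))
  expect_equal(panel_spectrum_overlap(LETTERS[1:5], spectra),
               c(P1 = 3L, P2 = 2L))
  set.seed(12)
  panel <- sample(LETTERS, 10)
  spectra <- lapply(stats::setNames(1:5, paste0("P", 1:5)),
                    function(i) sample(LETTERS, sample(2:20, 1)))
  got <- panel_spectrum_overlap(panel, spectra)
  exp <- vapply(spectra, function(g) length(intersect(panel, g)), integer(1))
  expect_equal(got, exp)
})

test_that("Kruskal-Wallis / Dunn pipeline matches rank-sum oracles", {
  # fully separated ranks, n = 10 per group: closed-form H
  g1 <- 1:10; g2 <- 21:30
  res <- compare_panels(list(A = g1, B = g2))
  N <- 20
  rbar <- c(mean(1:10), mean(11:20))
  H <- 12 / (N * (N + 1)) * sum(10 * (rbar - (N + 1) / 2)^2)
  expect_equal(res$kw_h, H)  # 14.2857...
  expect_equal(res$kw_p, stats::pchisq(H, 1, lower.tail = FALSE))

  # identical constants: no rank information at all
  flat <- compare_panels(list(A = rep(5, 4), B = rep(5, 4), C = rep(5, 4)))
  expect_equal(flat$kw_h, 0)
  expect_equal(flat$kw_p, 1)
  expect_true(all(flat$pairwise$z == 0))

  # Dunn z on a tie-free micro-example, from-scratch rank computation
  res <- compare_panels(list(A = c(1, 2), B = c(3, 4), C = c(5, 6)))
  se <- sqrt((6 * 7 / 12) * (1 / 2 + 1 / 2))
  zAB <- (mean(c(1, 2)) - mean(c(3, 4))) / se
  row <- res$pairwise[res$pairwise$group1 == "A" &
                        res$pairwise$group2 == "B", ]
  expect_equal(row$z, zAB)
  expect_equal(row$p, 2 * pnorm(-abs(zAB)))

  # tie-corrected variance: compare against explicit formula
  x <- c(1, 1, 2, 2, 2, 3, 4, 4)
  g <- factor(rep(c("A", "B"), each = 4))
  d <- dunn_test(x, g)
  r <- rank(x); tie <- table(x); Tt <- sum(tie^3 - tie); N <- 8
  se <- sqrt((N * (N + 1) / 12 - Tt / (12 * (N - 1))) * (1 / 4 + 1 / 4))
  expect_equal(d$z, (mean(r[1:4]) - mean(r[5:8])) / se)

  expect_error(compare_panels(list(A = 1:3)), "2 groups")
  expect_error(compare_panels(list(A = 1, B = 1:3)), ">= 2 values")
})

test_that("patient-specific panels dominate fixed panels on synthetic cohorts", {
  set.seed(31)
  p <- sim_params(n_patients = 15, seed = 31)
  spectra <- lapply(simulate_mutation_spectra(p), function(v) unique(v$gene))
  # a fixed 70-gene panel drawn from the same popularity law
  w <- seq_len(p$gene_pool_size)^(-p$popularity_alpha)
  fixed <- icptrack:::gene_pool_symbols(p$gene_pool_size)[
    sample.int(p$gene_pool_size, 70, prob = w)]
  fixed_counts <- panel_spectrum_overlap(fixed, spectra)
  icp_counts <- vapply(spectra, function(g)
    length(intersect(utils::head(g, 30), g)), integer(1))
  expect_gte(mean(icp_counts >= fixed_counts), 0.95)
})
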