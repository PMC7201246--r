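test_that("parameter validation catches inconsistent settings", {
  expect_error(sim_params(gene_pool_size = 100,
                          mutations_per_patient_range = c(50, 200)),
               "gene_pool_size")
  expect_error(sim_params(scenario_mix = c(responder = 0.5)), "sum to 1")
  expect_error(sim_params(scenario_mix = c(bogus = 1)), "unknown scenarios")
  expect_error(sim_params(hotspot_fraction = 1.5), "proportion")
  expect_error(trajectory_scenario("responder",
                                   sample_days = c(5, 10)), "start at 0")
  expect_error(trajectory_scenario("responder",
                                   sample_days = c(0, -3)), "nonnegative")
})

test_that("mutation spectra are seed-deterministic and within bounds", {
  p <- sim_params(n_patients = 5, seed = 99)
  a <- simulate_mutation_spectra(p)
  b <- simulate_mutation_spectra(p)
  expect_identical(a, b)
  rng <- p$mutations_per_patient_range
  for (v in a) {
    expect_gte(nrow(v), rng[1]); expect_lte(nrow(v), rng[2])
    expect_true(all(v$alt_reads <= v$total_reads))
    expect_equal(v$vaf, v$alt_reads / v$total_reads)
  }
})

test_that("degenerate popularity law gives total overlap, uniform law the
           hypergeometric expectation", {
  # alpha -> Inf: every mutation hits the same gene
  p <- sim_params(n_patients = 4, popularity_alpha = Inf, seed = 5)
  sp <- simulate_mutation_spectra(p)
  expect_equal(overlap_percentage(sp[[1]]$gene, sp[[2]]$gene), 100)

  # uniform popularity over a pool >> mutations/patient; disjoint patient
  # pairs so the averages are over independent draws
  m <- 60L; G <- 4000L
  p <- sim_params(n_patients = 200, popularity_alpha = 0, gene_pool_size = G,
                  mutations_per_patient_range = c(m, m), seed = 6)
  sp <- simulate_mutation_spectra(p)
  genes <- lapply(sp, function(v) unique(v$gene))
  got <- vapply(seq(1, 199, by = 2), function(i)
    overlap_percentage(genes[[i]], genes[[i + 1]]), numeric(1))
  # Monte-Carlo oracle: uniform sampling without replacement, same sizes
  set.seed(1000)
  mc <- replicate(3000, {
    a <- sample.int(G, m); b <- sample.int(G, m)
    i <- length(intersect(a, b))
    100 * i / (2 * m - i)
  })
  se <- sqrt(var(mc) / length(mc) + var(got) / length(got))
  expect_lt(abs(mean(got) - mean(mc)), 4 * se + 0.02)
})

test_that("median overlap increases with the popularity exponent", {
  med_overlap <- function(alpha, seed) {
    p <- sim_params(n_patients = 6, popularity_alpha = alpha,
                    gene_pool_size = 3000,
                    mutations_per_patient_range = c(60L, 120L), seed = seed)
    sp <- simulate_mutation_spectra(p)
    cohort_overlap_summary(lapply(sp, function(v)
      unique(v$gene)))$summary[["median"]]
  }
  seeds <- 1:20
  lo <- vapply(seeds, function(s) med_overlap(0.2, s), numeric(1))
  hi <- vapply(seeds, function(s) med_overlap(0.9, s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("neoepitope IC50s respect the configured range and binder mass", {
  p <- sim_params(seed = 8, ic50_log10_range = c(1, log10(400)),
                  epitopes_per_variant_mean = 1)
  v <- simulate_mutation_spectra(p)[[1]]
  neo <- simulate_neoepitopes(v, p)
  expect_true(all(neo$ic50_nm < 500))
  expect_true(all(nchar(neo$peptide) >= 8 & nchar(neo$peptide) <= 11))

  p <- sim_params(seed = 8, ic50_log10_range = c(log10(600), log10(50000)),
                  epitopes_per_variant_mean = 1)
  neo <- simulate_neoepitopes(v, p)
  expect_equal(sum(neo$ic50_nm < 500), 0)

  # default range: binder fraction within binomial noise of the
  # log-uniform mass below 500 nM
  p <- sim_params(seed = 9, epitopes_per_variant_mean = 5)
  big <- do.call(rbind, simulate_mutation_spectra(p))
  neo <- simulate_neoepitopes(big, p)
  pr <- (log10(500) - p$ic50_log10_range[1]) / diff(p$ic50_log10_range)
  n <- nrow(neo)
  expect_gt(n, 2000)
  expect_lt(abs(mean(neo$ic50_nm < 500) - pr), 3 * sqrt(pr * (1 - pr) / n))
})

test_that("serial ctDNA follows the scenario burden law", {
  p <- sim_params(seed = 12, depth_ctdna = 1e7, plasma_dropout = 0)
  v <- filter_variants(simulate_mutation_spectra(p)[[1]], quiet = TRUE)
  neo <- simulate_neoepitopes(v, p)
  panel <- design_panel(filter_binders(neo), v, patient_id = "P01")
  sc <- trajectory_scenario("responder")
  sim <- simulate_serial_ctdna(panel, sc, p, seed = 13)

  # near-noiseless depth: week-8 fold-change equals the burden multiplier
  loci <- panel$loci$locus
  fc <- fold_change(sim$ctdna, loci, week = 8, min_alt = 0)
  expect_equal(as.numeric(fc), sc$burden_fn(56), tolerance = 5e-3)

  # determinism contract
  sim2 <- simulate_serial_ctdna(panel, sc, p, seed = 13)
  expect_identical(sim, sim2)

  expect_error(
    simulate_serial_ctdna(panel, trajectory_scenario("responder",
                                                     sample_days = c(0, -7)),
                          p), "nonnegative")
})

test_that("resistant-clone trajectories lose every panel locus while the
           tumor grows", {
  p <- sim_params(seed = 14)
  v <- filter_variants(simulate_mutation_spectra(p)[[1]], quiet = TRUE)
  panel <- design_panel(NULL, v, patient_id = "P10")
  sim <- simulate_serial_ctdna(panel, trajectory_scenario("resistant_clone"),
                               p, seed = 15)
  late <- sim$ctdna[sim$ctdna$day >= 84, ]
  expect_true(all(late$alt_reads == 0))
  expect_true(all(diff(sim$burden$spd_mm2) > 0))
})

test_that("full cohorts are reproducible and expose scenario truth", {
  p <- sim_params(n_patients = 6, seed = 20)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a, b)
  expect_equal(sort(names(a$scenarios)), sort(names(a$variants)))
  expect_equal(nrow(a$outcomes), 6)
  expect_true(all(a$outcomes$pfs_days <= 540))

  # ever-detected rate always dominates the baseline rate
  for (id in names(a$panels)) {
    dr <- detection_rates(a$ctdna[[id]], a$panels[[id]]$loci$locus)
    expect_gte(dr[["ever_rate"]], dr[["baseline_rate"]])
  }
})
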