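#' @keywords internal
"_PACKAGE"

# Real NSCLC-recurrent gene symbols decorate the top popularity ranks so
# fixtures read naturally; the rest of the pool is synthetic.
.top_gene_symbols <- c(
  "TTN", "TP53", "MUC16", "CSMD3", "RYR2", "LRP1B", "USH2A", "ZFHX4",
  "KRAS", "XIRP2", "FLG", "SPTA1", "NAV3", "ZNF536", "FAT3", "CSMD1",
  "EGFR", "PCDH15", "COL11A1", "ANK2", "KEAP1", "STK11", "NF1", "RB1",
  "PIK3CA", "SMARCA4", "BRAF", "MET", "ERBB2", "APC")

gene_pool_symbols <- function(n) {
  syms <- .top_gene_symbols[seq_len(min(n, length(.top_gene_symbols)))]
  if (n > length(syms))
    syms <- c(syms, sprintf("SYNG%05d", seq_len(n - length(syms))))
  syms
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Simulate per-patient somatic mutation spectra
#'
#' Draws each patient's mutated genes without replacement from a shared
#' gene pool under a truncated power-law popularity distribution
#' (weight of rank r proportional to r^-alpha), so a few genes recur
#' across patients while most remain private. Read support is binomial
#' at the tissue depth around a Beta-distributed true VAF. Annotation
#' columns (hotspot, segmental-duplication, population frequency) are
#' Bernoulli flags at the configured fractions.
#'
#' @param params a [sim_params()] object; `params$seed`, when non-NULL,
#'   makes the draw reproducible.
#' @return a named list (one element per patient, `P01`, `P02`, ...) of
#'   somatic-variant data frames with columns `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `effect`, `alt_reads`, `total_reads`, `vaf`,
#'   `popfreq_max`, `is_hotspot`, `in_superdup`.
#' @export
simulate_mutation_spectra <- function(params) {
  validate_sim_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  G <- params$gene_pool_size
  genes <- gene_pool_symbols(G)
  w <- if (is.infinite(params$popularity_alpha)) c(1, rep(0, G - 1))
       else seq_len(G)^(-params$popularity_alpha)
  rng <- params$mutations_per_patient_range
  effects <- c("nonsynonymous_snv", "synonymous_snv", "indel")
  eff_p <- c(params$nonsyn_fraction, params$synonymous_fraction,
             1 - params$nonsyn_fraction - params$synonymous_fraction)
  bases <- c("A", "C", "G", "T")

  out <- vector("list", params$n_patients)
  names(out) <- sprintf("P%02d", seq_len(params$n_patients))
  for (i in seq_len(params$n_patients)) {
    m <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    if (is.infinite(params$popularity_alpha)) {
      # degenerate law: all mass on the top-ranked gene
      idx <- rep.int(1L, m)
    } else {
      idx <- sample.int(G, m, replace = FALSE, prob = w)
    }
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    vaf_true <- stats::rbeta(m, params$vaf_beta_params[1],
                             params$vaf_beta_params[2])
    total <- pmax(1L, stats::rpois(m, params$depth_tissue))
    altr <- stats::rbinom(m, total, vaf_true)
    out[[i]] <- data.frame(
      chrom = sample(paste0("chr", c(1:22, "X")), m, replace = TRUE),
      pos = sample.int(2.4e8, m, replace = TRUE),
      ref = ref, alt = alt, gene = genes[idx],
      effect = sample(effects, m, replace = TRUE, prob = eff_p),
      alt_reads = altr, total_reads = total, vaf = altr / total,
      popfreq_max = ifelse(
        stats::runif(m) < params$common_popfreq_fraction,
        stats::runif(m, 0, 0.2), 0),
      is_hotspot = stats::runif(m) < params$hotspot_fraction,
      in_superdup = stats::runif(m) < params$superdup_fraction,
      stringsAsFactors = FALSE)
  }
  out
}

#' Simulate neoepitope predictions for a variant table
#'
#' Each nonsynonymous variant yields a Poisson number of peptide-HLA
#' candidates whose predicted IC50 binding affinity is log-uniform on
#' `params$ic50_log10_range` (nM). Lower IC50 means stronger binding;
#' the fraction below the conventional 500 nM cutoff is therefore the
#' log-uniform mass of the range below log10(500).
#'
#' @param variants a somatic-variant data frame (one patient).
#' @param params a [sim_params()] object.
#' @return a neoepitope-candidate data frame with columns `variant_ref`,
#'   `gene`, `peptide`, `hla_allele`, `ic50_nm`, `rank_score`
#'   (`rank_score = ic50_nm`: lower is a stronger binder).
#' @export
simulate_neoepitopes <- function(variants, params) {
  stopifnot(is.data.frame(variants), nrow(variants) > 0)
  if (!is.null(params$seed)) set.seed(params$seed)
  nsv <- variants[variants$effect == "nonsynonymous_snv", , drop = FALSE]
  k <- if (nrow(nsv)) stats::rpois(nrow(nsv), params$epitopes_per_variant_mean)
       else integer()
  n <- sum(k)
  if (n == 0L) {
    return(data.frame(variant_ref = character(), gene = character(),
                      peptide = character(), hla_allele = character(),
                      ic50_nm = numeric(), rank_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- rep.int(seq_len(nrow(nsv)), k)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pep_len <- sample(8:11, n, replace = TRUE)
  peptide <- vapply(pep_len, function(L)
    paste(sample(aa, L, replace = TRUE), collapse = ""), "")
  ic50 <- 10^stats::runif(n, params$ic50_log10_range[1],
                          params$ic50_log10_range[2])
  data.frame(
    variant_ref = variant_key(nsv$chrom[rows], nsv$pos[rows],
                              nsv$ref[rows], nsv$alt[rows]),
    gene = nsv$gene[rows],
    peptide = peptide,
    hla_allele = sample(c("HLA-A*02:01", "HLA-A*11:01", "HLA-A*24:02",
                          "HLA-B*40:01", "HLA-C*07:02"), n, replace = TRUE),
    ic50_nm = ic50, rank_score = ic50,
    stringsAsFactors = FALSE)
}

#' Simulate serial ctDNA, tumor burden and outcome for one patient
#'
#' For coupled panel loci the plasma MAF at day `t` equals the baseline
#' locus MAF times the scenario's ctDNA multiplier (which equals the
#' burden multiplier except where the scenario decouples them); observed
#' alt reads are binomial at the plasma depth. Baseline plasma MAF per
#' locus is the tissue VAF times a log-normal shedding factor, with a
#' configurable fraction of loci never shed (MAF 0 throughout). SPD is
#' sampled on the imaging schedule as baseline SPD times the burden
#' multiplier. PFS is exponential with a scenario-dependent mean and
#' administrative censoring at 540 days.
#'
#' @param panel a `panel_design` object (see [design_panel()]).
#' @param scenario a [trajectory_scenario()] object.
#' @param params a [sim_params()] object.
#' @param seed optional integer overriding `params$seed`.
#' @return a list with `ctdna` (long data frame: `patient_id`, `locus`,
#'   `day`, `alt_reads`, `depth`, `maf`), `burden` (`patient_id`, `day`,
#'   `spd_mm2`) and `outcome` (`patient_id`, `scenario`, `pfs_days`,
#'   `event`, `best_response`).
#' @export
simulate_serial_ctdna <- function(panel, scenario, params, seed = NULL) {
  stopifnot(inherits(panel, "panel_design"), nrow(panel$loci) > 0,
            inherits(scenario, "trajectory_scenario"))
  seed <- if (is.null(seed)) params$seed else as.integer(seed)
  if (!is.null(seed)) set.seed(seed)
  loci <- panel$loci
  nl <- nrow(loci)
  days <- scenario$sample_days
  if (any(days < 0)) stop("negative sampling days are not allowed")

  shed <- stats::rlnorm(nl, params$shed_meanlog, params$shed_sdlog)
  shed[stats::runif(nl) < params$plasma_dropout] <- 0
  base_maf <- pmin(0.6, loci$vaf * shed)
  coupled <- stats::runif(nl) < scenario$ctdna_coupling

  mult_c <- scenario$ctdna_fn(days)
  maf_mat <- outer(base_maf, rep(1, length(days)))
  maf_mat[coupled, ] <- base_maf[coupled] %o% mult_c
  maf_mat <- pmin(maf_mat, 1)
  alt <- matrix(stats::rbinom(length(maf_mat), params$depth_ctdna, maf_mat),
                nrow = nl)
  ctdna <- data.frame(
    patient_id = panel$patient_id,
    locus = rep(loci$locus, times = length(days)),
    day = rep(days, each = nl),
    alt_reads = as.vector(alt),
    depth = params$depth_ctdna,
    stringsAsFactors = FALSE)
  ctdna$maf <- ctdna$alt_reads / ctdna$depth

  base_spd <- stats::rlnorm(1, log(2500), 0.5)
  idays <- scenario$imaging_days
  burden <- data.frame(patient_id = panel$patient_id, day = idays,
                       spd_mm2 = base_spd * scenario$burden_fn(idays),
                       stringsAsFactors = FALSE)

  pfs <- stats::rexp(1, 1 / scenario$pfs_mean_days)
  event <- pfs <= 540
  outcome <- data.frame(
    patient_id = panel$patient_id, scenario = scenario$name,
    pfs_days = round(min(pfs, 540)), event = event,
    best_response = switch(scenario$name,
      responder = sample(c("CR", "PR"), 1, prob = c(0.15, 0.85)),
      nonresponder = "SD", progressor = "PD", resistant_clone = "PD",
      occult_relapse = "PR"),
    stringsAsFactors = FALSE)
  list(ctdna = ctdna, burden = burden, outcome = outcome)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the generator end to end: mutation spectra, neoepitope
#' predictions, variant filtering, panel design per patient, scenario
#' assignment from `params$scenario_mix` (largest-remainder rounding so
#' every listed scenario with positive mass appears when the cohort is
#' large enough), and serial ctDNA / burden / outcome simulation.
#'
#' @param params a [sim_params()] object.
#' @return a list with per-patient elements `variants` (raw spectra),
#'   `retained` (post-filter), `neoepitopes`, `panels`, `ctdna`,
#'   `burden`, `outcomes` (one row per patient, includes the true
#'   scenario label), and `scenarios` (named character vector).
#' @export
simulate_cohort <- function(params) {
  validate_sim_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  sub <- sample.int(2^31 - 2, 4L)

  p2 <- params; p2$seed <- sub[1]
  spectra <- simulate_mutation_spectra(p2)
  ids <- names(spectra)

  scen <- assign_scenarios(params$scenario_mix, length(ids), seed = sub[2])
  names(scen) <- ids

  retained <- lapply(spectra, filter_variants, quiet = TRUE)
  neo <- vector("list", length(ids)); names(neo) <- ids
  panels <- vector("list", length(ids)); names(panels) <- ids
  ctdna <- vector("list", length(ids)); names(ctdna) <- ids
  burden <- vector("list", length(ids)); names(burden) <- ids
  outcomes <- vector("list", length(ids)); names(outcomes) <- ids

  for (i in seq_along(ids)) {
    id <- ids[i]
    p3 <- params; p3$seed <- (sub[3] + 1000L * i) %% (2^31 - 1)
    neo[[id]] <- simulate_neoepitopes(retained[[id]], p3)
    binders <- filter_binders(neo[[id]])
    panels[[id]] <- design_panel(binders, retained[[id]], patient_id = id)
    # coverage is of the dominant (binding) neoepitope repertoire
    if (nrow(binders))
      panels[[id]]$coverage_fraction <- coverage_fraction(panels[[id]],
                                                          binders)
    sc <- trajectory_scenario(scen[id])
    sim <- simulate_serial_ctdna(panels[[id]], sc, params,
                                 seed = (sub[4] + 1000L * i) %% (2^31 - 1))
    ctdna[[id]] <- sim$ctdna
    burden[[id]] <- sim$burden
    outcomes[[id]] <- sim$outcome
  }
  list(params = params, variants = spectra, retained = retained,
       neoepitopes = neo, panels = panels, ctdna = ctdna, burden = burden,
       outcomes = do.call(rbind, c(outcomes, list(make.row.names = FALSE))),
       scenarios = scen)
}

# Largest-remainder apportionment of scenarios, then a seeded shuffle.
assign_scenarios <- function(mix, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mix <- mix[mix > 0]
  quota <- mix * n
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  sample(rep(names(mix), times = counts))
}
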