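#' Simulation parameters for a synthetic ctDNA-monitoring cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults
#' describe a small advanced-NSCLC cohort under checkpoint blockade:
#' mutation loads between 38 and 496 non-silent mutations per patient,
#' a shared Zipf-like gene "popularity" law so that a handful of genes
#' (TP53/TTN/MUC16-like) recur across patients while most mutated genes
#' stay private, tissue sequencing at ~500x and plasma panel sequencing
#' at ~2000x, and a mix of on-treatment trajectory scenarios.
#'
#' @param n_patients number of patients to simulate.
#' @param gene_pool_size size of the shared gene pool genes are drawn from.
#'   Must be at least `max(mutations_per_patient_range)`.
#' @param popularity_alpha exponent of the truncated power law giving each
#'   gene's relative mutability (rank^-alpha). Larger values concentrate
#'   mutations on few genes and increase inter-patient overlap; `Inf`
#'   degenerates to a single universally mutated gene.
#' @param mutations_per_patient_range integer interval `c(low, high)` for the
#'   per-patient count of somatic mutations (uniform draw).
#' @param hotspot_fraction proportion of variants flagged as cancer hotspots.
#' @param vaf_beta_params `c(shape1, shape2)` of the Beta law for true tissue
#'   variant allele fractions.
#' @param ic50_log10_range `c(low, high)` range (log10 nM) of predicted
#'   MHC-binding IC50 values; candidates are log-uniform on this range.
#' @param depth_tissue mean sequencing depth of the tumor-tissue assay.
#' @param depth_ctdna sequencing depth of the plasma panel assay.
#' @param scenario_mix named proportions over the five trajectory scenarios
#'   (must sum to 1); see [trajectory_scenario()].
#' @param nonsyn_fraction,synonymous_fraction proportions of variant effects;
#'   the remainder are small indels.
#' @param superdup_fraction proportion of variants falling in segmental
#'   duplications (`genomicSuperDups`).
#' @param common_popfreq_fraction proportion of variants carrying a population
#'   frequency above zero (drawn uniform on (0, 0.2]).
#' @param epitopes_per_variant_mean Poisson mean for the number of predicted
#'   peptide-HLA candidates per nonsynonymous variant.
#' @param shed_meanlog,shed_sdlog log-normal parameters of the per-locus
#'   plasma shedding factor linking tissue VAF to baseline plasma MAF.
#' @param plasma_dropout proportion of panel loci never shed into plasma
#'   (baseline and all later MAFs are zero for these loci).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#'
#' @return an object of class `sim_params` (a validated list).
#' @seealso [simulate_cohort()], [trajectory_scenario()]
#' @export
sim_params <- function(n_patients = 10L,
                       gene_pool_size = 12000L,
                       popularity_alpha = 0.4,
                       mutations_per_patient_range = c(38L, 496L),
                       hotspot_fraction = 0.04,
                       vaf_beta_params = c(2, 8),
                       ic50_log10_range = c(1, log10(50000)),
                       depth_tissue = 500L,
                       depth_ctdna = 2000L,
                       scenario_mix = c(responder = 0.3,
                                        nonresponder = 0.2,
                                        progressor = 0.2,
                                        resistant_clone = 0.15,
                                        occult_relapse = 0.15),
                       nonsyn_fraction = 0.82,
                       synonymous_fraction = 0.10,
                       superdup_fraction = 0.02,
                       common_popfreq_fraction = 0.03,
                       epitopes_per_variant_mean = 0.22,
                       shed_meanlog = log(0.1),
                       shed_sdlog = 2.0,
                       plasma_dropout = 0.05,
                       seed = NULL) {
  p <- list(n_patients = as.integer(n_patients),
            gene_pool_size = as.integer(gene_pool_size),
            popularity_alpha = popularity_alpha,
            mutations_per_patient_range = as.integer(mutations_per_patient_range),
            hotspot_fraction = hotspot_fraction,
            vaf_beta_params = vaf_beta_params,
            ic50_log10_range = ic50_log10_range,
            depth_tissue = as.integer(depth_tissue),
            depth_ctdna = as.integer(depth_ctdna),
            scenario_mix = scenario_mix,
            nonsyn_fraction = nonsyn_fraction,
            synonymous_fraction = synonymous_fraction,
            superdup_fraction = superdup_fraction,
            common_popfreq_fraction = common_popfreq_fraction,
            epitopes_per_variant_mean = epitopes_per_variant_mean,
            shed_meanlog = shed_meanlog,
            shed_sdlog = shed_sdlog,
            plasma_dropout = plasma_dropout,
            seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  stopifnot(p$n_patients >= 1L,
            length(p$mutations_per_patient_range) == 2L,
            p$mutations_per_patient_range[1] >= 1L,
            p$mutations_per_patient_range[1] <= p$mutations_per_patient_range[2])
  if (p$gene_pool_size < p$mutations_per_patient_range[2])
    stop("gene_pool_size must be >= the maximum mutations per patient")
  props <- c(p$hotspot_fraction, p$superdup_fraction, p$common_popfreq_fraction,
             p$nonsyn_fraction, p$synonymous_fraction, p$plasma_dropout,
             p$scenario_mix)
  if (any(props < 0 | props > 1))
    stop("all proportion parameters must lie in [0, 1]")
  if (p$nonsyn_fraction + p$synonymous_fraction > 1)
    stop("nonsyn_fraction + synonymous_fraction must be <= 1")
  if (abs(sum(p$scenario_mix) - 1) > 1e-8)
    stop("scenario_mix must sum to 1")
  bad <- setdiff(names(p$scenario_mix), scenario_names())
  if (length(bad)) stop("unknown scenarios: ", paste(bad, collapse = ", "))
  stopifnot(all(p$vaf_beta_params > 0),
            diff(p$ic50_log10_range) >= 0,
            p$depth_tissue >= 1L, p$depth_ctdna >= 1L)
  invisible(p)
}

scenario_names <- function() {
  c("responder", "nonresponder", "progressor", "resistant_clone",
    "occult_relapse")
}

#' On-treatment trajectory scenarios
#'
#' Each scenario couples a tumor-burden multiplier curve (relative to
#' baseline SPD, the sum of products of perpendicular lesion diameters)
#' with a ctDNA multiplier curve applied to the coupled panel loci:
#'
#' * `responder` — exponential tumor shrinkage reaching well below half
#'   the baseline burden by day 56, ctDNA fully coupled.
#' * `nonresponder` — essentially stable disease.
#' * `progressor` — exponential burden growth.
#' * `resistant_clone` — burden grows while the ctDNA signal of every
#'   panel locus decays linearly to zero by day 84: outgrowth of a clone
#'   that does not carry the monitored neoantigens, so the panel loses
#'   the tumor entirely.
#' * `occult_relapse` — initial response, then from day 239 the ctDNA
#'   level climbs to 14x baseline by day 351 while the imaged burden
#'   stays low: relapse outside the surveillance field.
#'
#' Plasma draws default to days 0, 28, 56, 84 and then every 42 days;
#' imaging follows the six-weekly (42-day) schedule of response
#' evaluation. `occult_relapse` extends follow-up to a year so the late
#' re-rise is observable.
#'
#' @param name one of `"responder"`, `"nonresponder"`, `"progressor"`,
#'   `"resistant_clone"`, `"occult_relapse"`.
#' @param ctdna_coupling fraction of panel loci whose plasma MAF follows
#'   the scenario's ctDNA multiplier; uncoupled loci stay at baseline level.
#' @param sample_days plasma sampling days (must start at 0, ascending).
#' @param horizon_days last day of follow-up used for default schedules.
#'
#' @return an object of class `trajectory_scenario`: a list with `name`,
#'   `burden_fn(t)`, `ctdna_fn(t)`, `ctdna_coupling`, `sample_days`,
#'   `imaging_days` and `pfs_mean_days`.
#' @export
trajectory_scenario <- function(name,
                                ctdna_coupling = 1,
                                sample_days = NULL,
                                horizon_days = NULL) {
  name <- match.arg(name, scenario_names())
  if (is.null(horizon_days))
    horizon_days <- if (name == "occult_relapse") 364 else 168
  if (is.null(sample_days)) {
    sample_days <- c(0, 28, 56, 84)
    if (horizon_days >= 126)
      sample_days <- c(sample_days, seq(126, horizon_days, by = 42))
  }
  sample_days <- as.numeric(sample_days)
  if (any(sample_days < 0)) stop("sample days must be nonnegative")
  if (sample_days[1] != 0 || is.unsorted(sample_days, strictly = TRUE))
    stop("sample_days must be strictly ascending and start at 0 (baseline)")
  stopifnot(ctdna_coupling >= 0, ctdna_coupling <= 1)

  burden_fn <- switch(name,
    responder       = function(t) exp(-0.02 * t),
    nonresponder    = function(t) exp(-0.0005 * t),
    progressor      = function(t) exp(0.009 * t),
    resistant_clone = function(t) exp(0.009 * t),
    occult_relapse  = function(t) pmax(0.25, exp(-0.025 * t)))
  ctdna_fn <- switch(name,
    resistant_clone = function(t) pmax(0, 1 - t / 84),
    occult_relapse  = function(t) {
      lo <- pmax(0.25, exp(-0.025 * t))
      ifelse(t < 239, lo, 0.25 * (14 / 0.25)^((t - 239) / (351 - 239)))
    },
    burden_fn)

  sc <- list(name = name, burden_fn = burden_fn, ctdna_fn = ctdna_fn,
             ctdna_coupling = ctdna_coupling, sample_days = sample_days,
             imaging_days = seq(0, horizon_days, by = 42),
             pfs_mean_days = switch(name, responder = 400, nonresponder = 160,
                                    progressor = 70, resistant_clone = 70,
                                    occult_relapse = 290))
  if (any(burden_fn(sample_days) <= 0))
    stop("burden multiplier must stay positive at all sampled days")
  if (name == "responder" && burden_fn(56) > 0.5)
    stop("responder scenario must reach <= 0.5x baseline burden by day 56")
  class(sc) <- "trajectory_scenario"
  sc
}
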