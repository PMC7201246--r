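#' Build a pipeline run configuration
#'
#' A flat configuration for [run_pipeline()]. Exactly one of
#' `sim` (a [sim_params()] block, simulate mode) or `inputs` (named
#' paths `variants`, `neoepitopes`, `ctdna`, `burden`, `outcomes`;
#' real-input mode) must be given. Every analysis threshold is a named
#' key with the conventional default.
#'
#' @param sim a [sim_params()] object, or `NULL`.
#' @param inputs named list of input file paths, or `NULL`.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed for simulate mode.
#' @param binder_nm MHC-binder IC50 cutoff (nM).
#' @param vaf_min,hotspot_vaf_min,superdup_vaf_max,popfreq_cutoff
#'   variant-retention thresholds (see [filter_variants()]).
#' @param min_alt ctDNA detection threshold (mutant reads).
#' @param response_week week of the ctDNA response assessment.
#' @param decline_fraction fold-change defining a ctDNA responder.
#' @param pairing_window_days imaging/draw pairing window.
#' @param coding_mb coding footprint for TMB.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = NULL, inputs = NULL, out_dir = tempfile("icp_"),
                       seed = 1L, binder_nm = 500, vaf_min = 0.03,
                       hotspot_vaf_min = 0.01, superdup_vaf_max = 0.2,
                       popfreq_cutoff = 0.05, min_alt = 3L,
                       response_week = 8L, decline_fraction = 0.5,
                       pairing_window_days = 14L, coding_mb = 38) {
  if (is.null(sim) == is.null(inputs))
    stop("exactly one of `sim` and `inputs` must be supplied")
  stopifnot(binder_nm > 0, vaf_min >= 0, vaf_min <= 1,
            hotspot_vaf_min >= 0, hotspot_vaf_min <= vaf_min,
            decline_fraction > 0, decline_fraction < 1,
            min_alt >= 1, response_week >= 1, pairing_window_days >= 0)
  if (!is.null(inputs)) {
    need <- c("variants", "neoepitopes", "ctdna", "burden", "outcomes")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop("missing input paths: ",
                           paste(miss, collapse = ", "))
  }
  structure(list(sim = sim, inputs = inputs, out_dir = out_dir,
                 seed = as.integer(seed), binder_nm = binder_nm,
                 vaf_min = vaf_min, hotspot_vaf_min = hotspot_vaf_min,
                 superdup_vaf_max = superdup_vaf_max,
                 popfreq_cutoff = popfreq_cutoff,
                 min_alt = as.integer(min_alt),
                 response_week = as.integer(response_week),
                 decline_fraction = decline_fraction,
                 pairing_window_days = as.integer(pairing_window_days),
                 coding_mb = coding_mb),
            class = "run_config")
}

config_hash <- function(config) {
  c2 <- unclass(config)
  c2$out_dir <- NULL  # a run's identity must not depend on where it writes
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(c2, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes filter -> panel design -> cohort overlap -> ctDNA kinetics
#' -> outcomes on every patient, writes all stage outputs plus a run
#' manifest (config hash, seed, per-stage row counts) under
#' `config$out_dir`, and returns the results invisibly. Runs are
#' idempotent for a fixed seed: the manifest is byte-identical across
#' repeats. A patient without a baseline plasma draw is excluded from
#' the fold-change cohort summaries, with the reason recorded in the
#' per-patient kinetics table.
#'
#' @param config a [run_config()] object.
#' @return (invisibly) a list with `cohort`, `overlap`, `recurrence`,
#'   `kinetics` (per-patient data frame), `outcomes` (tests, or `NULL`
#'   when a class is absent), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- load_or_simulate(config)
  ids <- names(cohort$retained)
  if (length(ids) == 0) stop("pipeline aborted: empty patient list")

  # -- overlap stage (retained nonsynonymous spectra) ------------------
  spectra <- lapply(cohort$retained, function(v)
    unique(v$gene[v$effect == "nonsynonymous_snv"]))
  overlap <- cohort_overlap_summary(spectra)
  recurrence <- recurrence_stats(spectra)

  # -- kinetics stage --------------------------------------------------
  kin <- lapply(ids, function(id) {
    tryCatch(
      patient_kinetics(id, cohort, config),
      error = function(e) stop("stage kinetics failed for patient ", id,
                               ": ", conditionMessage(e), call. = FALSE))
  })
  kinetics <- do.call(rbind, c(kin, list(make.row.names = FALSE)))

  # -- outcomes stage --------------------------------------------------
  out_tab <- merge(cohort$outcomes,
                   kinetics[, c("patient_id", "ctdna_class")],
                   by = "patient_id")
  outcomes <- NULL
  cls <- out_tab$ctdna_class[!is.na(out_tab$ctdna_class)]
  if (length(unique(cls)) == 2 && any(out_tab$event)) {
    keep <- !is.na(out_tab$ctdna_class)
    outcomes <- list(
      km = km_logrank(out_tab$pfs_days[keep], out_tab$event[keep],
                      out_tab$ctdna_class[keep]),
      cox = cox_hr(out_tab$pfs_days[keep], out_tab$event[keep],
                   out_tab$ctdna_class[keep],
                   reference = "ctDNA_responder"))
  }
  ordering <- response_ordering_report(kinetics$patient_id,
                                       kinetics$fc_week12,
                                       out_tab$best_response[
                                         match(kinetics$patient_id,
                                               out_tab$patient_id)],
                                       kinetics$tmb)

  # -- write outputs ---------------------------------------------------
  od <- config$out_dir
  write_variant_table(cohort$retained, file.path(od, "variants_retained.tsv"))
  pdir <- file.path(od, "panels")
  dir.create(pdir, showWarnings = FALSE)
  for (id in ids)
    write_panel(cohort$panels[[id]],
                bed_path = file.path(pdir, paste0(id, ".bed")),
                manifest_path = file.path(pdir, paste0(id, ".tsv")))
  utils::write.csv(overlap$pairs, file.path(od, "overlap_pairs.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(kinetics, file.path(od, "kinetics.csv"),
                   row.names = FALSE, quote = FALSE)
  summary_json <- list(
    overlap = as.list(overlap$summary),
    recurrence = recurrence[c("union_size", "n_shared_ge2", "n_shared_gt3",
                              "pct_ge2", "pct_gt3")],
    outcomes = if (!is.null(outcomes)) list(
      km_p = outcomes$km$p, hr = outcomes$cox$hr,
      hr_ci = c(outcomes$cox$ci_low, outcomes$cox$ci_high),
      separation = outcomes$cox$separation),
    ordering_fisher_p = ordering$fisher_p)
  jsonlite::write_json(summary_json, file.path(od, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")

  manifest <- list(
    tool = "icptrack",
    version = as.character(utils::packageVersion("icptrack")),
    mode = if (is.null(config$sim)) "input" else "simulate",
    seed = config$seed,
    config_hash = config_hash(config),
    stages = list(
      patients = length(ids),
      variants = sum(vapply(cohort$variants, nrow, 1L)),
      retained = sum(vapply(cohort$retained, nrow, 1L)),
      panel_loci = sum(vapply(cohort$panels,
                              function(p) nrow(p$loci), 1L)),
      ctdna_rows = sum(vapply(cohort$ctdna, nrow, 1L)),
      burden_rows = sum(vapply(cohort$burden, nrow, 1L)),
      outcome_rows = nrow(cohort$outcomes)))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, overlap = overlap,
                 recurrence = recurrence, kinetics = kinetics,
                 outcomes = outcomes, ordering = ordering,
                 manifest = manifest))
}

load_or_simulate <- function(config) {
  if (!is.null(config$sim)) {
    params <- config$sim
    params$seed <- config$seed
    return(simulate_cohort(params))
  }
  ip <- config$inputs
  variants <- read_variant_table(ip$variants)
  neo_all <- utils::read.delim(ip$neoepitopes, stringsAsFactors = FALSE)
  neo <- split(neo_all[setdiff(names(neo_all), "patient_id")],
               neo_all$patient_id)
  ctdna <- read_ctdna_csv(ip$ctdna)
  burden <- read_burden_csv(ip$burden)
  outcomes <- read_outcomes_csv(ip$outcomes)

  ids <- names(variants)
  retained <- lapply(variants, filter_variants,
                     vaf_min = config$vaf_min,
                     hotspot_vaf_min = config$hotspot_vaf_min,
                     superdup_vaf_max = config$superdup_vaf_max,
                     popfreq_cutoff = config$popfreq_cutoff, quiet = TRUE)
  panels <- lapply(ids, function(id) {
    cand <- neo[[id]]
    binders <- if (is.null(cand) || nrow(cand) == 0) cand
               else filter_binders(cand, config$binder_nm)
    p <- design_panel(binders, retained[[id]], patient_id = id)
    if (!is.null(cand) && nrow(cand) > 0)
      p$coverage_fraction <- coverage_fraction(p, cand)
    p
  })
  names(panels) <- ids
  list(params = NULL, variants = variants, retained = retained,
       neoepitopes = neo, panels = panels,
       ctdna = ctdna[ids], burden = burden[ids],
       outcomes = outcomes, scenarios = NULL)
}

patient_kinetics <- function(id, cohort, config) {
  panel_loci <- cohort$panels[[id]]$loci$locus
  series <- cohort$ctdna[[id]]
  burden <- cohort$burden[[id]]
  rates <- detection_rates(series, panel_loci, config$min_alt)

  has_baseline <- 0 %in% series$day
  fc8 <- fc12 <- NA_real_; fc_day <- NA_real_
  excluded <- NA_character_
  if (!has_baseline) {
    excluded <- "no_baseline_sample"
  } else {
    fc8 <- fold_change(series, panel_loci, week = config$response_week,
                       min_alt = config$min_alt)
    fc_day <- if (!is.na(fc8)) attr(fc8, "day") else NA_real_
    if (is.na(fc8)) excluded <- attr(fc8, "reason")
    fc12 <- fold_change(series, panel_loci, week = 12L,
                        min_alt = config$min_alt)
  }
  cls <- if (is.na(fc8)) NA_character_ else
    ifelse(fc8 <= config$decline_fraction,
           "ctDNA_responder", "ctDNA_nonresponder")

  days <- sort(unique(series$day))
  mm <- vapply(days, mean_maf, numeric(1), series = series,
               panel_loci = panel_loci, min_alt = config$min_alt)
  tth_ctdna <- if (mm[1] > 0) time_to_half(days, mm) else NA_real_
  tth_spd <- time_to_half(burden$day, burden$spd_mm2)
  conc <- burden_concordance(series, burden, panel_loci,
                             config$pairing_window_days, config$min_alt)
  tmb <- compute_tmb(cohort$retained[[id]], config$coding_mb)

  data.frame(patient_id = id,
             baseline_rate = rates[["baseline_rate"]],
             ever_rate = rates[["ever_rate"]],
             fc_week8 = as.numeric(fc8), fc_day = fc_day,
             fc_week12 = as.numeric(fc12),
             ctdna_class = cls, excluded_reason = excluded,
             tth_ctdna_days = tth_ctdna, tth_spd_days = tth_spd,
             per_locus_r = conc$per_locus_r,
             mean_level_r = conc$mean_level_r, n_pairs = conc$n_pairs,
             tmb = tmb, stringsAsFactors = FALSE)
}

#' Write a small bundled demo cohort
#'
#' Emits a 10-patient synthetic cohort spanning all five trajectory
#' scenarios in the flat input formats the pipeline consumes
#' (`variants.tsv`, `neoepitopes.tsv`, `ctdna.csv`, `burden.csv`,
#' `outcomes.csv`, plus `scenarios.txt` recording the truth labels),
#' sized so the full pipeline runs in well under a minute.
#'
#' @param out_dir writable output directory.
#' @param seed integer seed; different seeds give different cohorts.
#' @return named character vector of the file paths written.
#' @export
make_fixtures <- function(out_dir, seed = 20200321L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0)
    stop("output directory is not writable: ", out_dir)
  params <- sim_params(n_patients = 10L, seed = seed)
  cohort <- simulate_cohort(params)
  neo <- do.call(rbind, Map(function(id, v)
    if (nrow(v)) cbind(patient_id = id, v) else NULL,
    names(cohort$neoepitopes), cohort$neoepitopes))
  paths <- c(
    variants = write_variant_table(cohort$variants,
                                   file.path(out_dir, "variants.tsv")),
    neoepitopes = {
      p <- file.path(out_dir, "neoepitopes.tsv")
      utils::write.table(neo, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p
    },
    ctdna = write_ctdna_csv(cohort$ctdna, file.path(out_dir, "ctdna.csv")),
    burden = write_burden_csv(cohort$burden,
                              file.path(out_dir, "burden.csv")),
    outcomes = {
      p <- file.path(out_dir, "outcomes.csv")
      utils::write.csv(cohort$outcomes, p, row.names = FALSE,
                       quote = FALSE)
      p
    },
    scenarios = {
      p <- file.path(out_dir, "scenarios.txt")
      writeLines(paste(names(cohort$scenarios), cohort$scenarios,
                       sep = "\t"), p)
      p
    })
  paths
}
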