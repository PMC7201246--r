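# A ctDNA series is a long data frame (one patient): locus, day,
# alt_reads, depth. A locus counts as detected when alt_reads >= min_alt
# (default 3) — plasma assays need a handful of concordant mutant reads
# before a call is credible, and the exact limit is configurable.

ctdna_maf <- function(series) series$alt_reads / series$depth

#' Baseline and ever-detected panel detection rates
#'
#' `baseline_rate` is the fraction of panel loci with a detected signal
#' in the day-0 draw; `ever_rate` the fraction detected in at least one
#' draw over follow-up. Loci on the panel but absent from a draw count
#' as undetected at that draw. Without a baseline sample the baseline
#' rate is `NA` and the ever rate is still computed.
#'
#' @param series ctDNA long data frame (`locus`, `day`, `alt_reads`,
#'   `depth`).
#' @param panel_loci character vector of panel locus keys.
#' @param min_alt detection threshold on mutant reads.
#' @return named numeric vector `c(baseline_rate, ever_rate)`.
#' @export
detection_rates <- function(series, panel_loci, min_alt = 3L) {
  stopifnot(length(panel_loci) > 0)
  det <- series[series$alt_reads >= min_alt, , drop = FALSE]
  ever <- mean(panel_loci %in% det$locus)
  base <- if (0 %in% series$day) {
    mean(panel_loci %in% det$locus[det$day == 0])
  } else NA_real_
  c(baseline_rate = base, ever_rate = ever)
}

#' Mean mutant allele fraction at a sampling day
#'
#' Arithmetic mean of the per-locus MAF over all panel loci at the given
#' day. Undetected loci (below `min_alt` mutant reads, or missing from
#' the draw) contribute 0 by default; `detected_only = TRUE` averages
#' detected loci alone.
#'
#' @inheritParams detection_rates
#' @param day sampling day; must have at least one measurement.
#' @param detected_only average over detected loci only.
#' @return mean MAF (proportion).
#' @export
mean_maf <- function(series, day, panel_loci, min_alt = 3L,
                     detected_only = FALSE) {
  s <- series[series$day == day, , drop = FALSE]
  if (nrow(s) == 0) stop("no ctDNA sample at day ", day)
  maf <- ctdna_maf(s)
  maf[s$alt_reads < min_alt] <- 0
  full <- stats::setNames(numeric(length(panel_loci)), panel_loci)
  on_panel <- s$locus %in% panel_loci
  full[s$locus[on_panel]] <- maf[on_panel]
  if (detected_only) {
    d <- full[full > 0]
    if (!length(d)) return(0)
    return(mean(d))
  }
  mean(full)
}

#' Fold-change in mean MAF from baseline to a given week
#'
#' Uses the draw nearest to day `7 * week` within `window_days`; an
#' exact tie in distance resolves to the earlier draw. A zero baseline
#' makes the fold-change undefined (`NA` with attribute
#' `reason = "baseline_zero"`); no draw in the window gives `NA` with
#' `reason = "no_sample"`.
#'
#' @inheritParams mean_maf
#' @param week target week after the first infusion.
#' @param window_days half-width of the admissible window around the
#'   target day.
#' @return the ratio `mean_maf(nearest day) / mean_maf(0)`, with
#'   attribute `day` giving the draw used.
#' @export
fold_change <- function(series, panel_loci, week = 8L, window_days = 14L,
                        min_alt = 3L) {
  if (!(0 %in% series$day)) stop("no baseline (day 0) sample")
  base <- mean_maf(series, 0, panel_loci, min_alt)
  if (base == 0)
    return(structure(NA_real_, reason = "baseline_zero"))
  target <- 7 * week
  days <- sort(unique(series$day))
  cand <- days[abs(days - target) <= window_days]
  if (!length(cand))
    return(structure(NA_real_, reason = "no_sample"))
  cand <- cand[order(abs(cand - target), cand)]
  d <- cand[1]
  structure(mean_maf(series, d, panel_loci, min_alt) / base, day = d)
}

#' Classify the week-8 ctDNA response
#'
#' A decrease of at least 50% in mean MAF by week 8 (fold-change
#' `<= 0.5`, boundary inclusive) defines a ctDNA responder.
#'
#' @param fc_week8 fold-change(s) from [fold_change()].
#' @return character vector, `"ctDNA_responder"` / `"ctDNA_nonresponder"`
#'   (`NA` propagates).
#' @export
classify_response <- function(fc_week8) {
  ifelse(is.na(fc_week8), NA_character_,
         ifelse(fc_week8 <= 0.5, "ctDNA_responder", "ctDNA_nonresponder"))
}

#' Time to a 50% decline of a longitudinal marker
#'
#' First day at which linear interpolation between consecutive
#' measurements crosses half the baseline value; exact if a measurement
#' equals the threshold. `NA` ("not reached") when the series never
#' crosses.
#'
#' @param day,value paired numeric vectors (days ascending, >= 2 points,
#'   positive baseline).
#' @return day of first crossing, or `NA_real_` if never reached.
#' @export
time_to_half <- function(day, value) {
  stopifnot(length(day) == length(value), length(day) >= 2)
  o <- order(day)
  day <- day[o]; value <- value[o]
  if (value[1] <= 0) stop("baseline value must be positive")
  thr <- value[1] / 2
  for (i in seq_along(day)) {
    if (value[i] <= thr) {
      if (i == 1) return(day[1])
      if (value[i] == thr) return(day[i])
      return(day[i - 1] + (day[i] - day[i - 1]) *
               (value[i - 1] - thr) / (value[i - 1] - value[i]))
    }
  }
  NA_real_
}

#' Concordance between ctDNA level and radiological tumor burden
#'
#' Pairs each imaging timepoint with the nearest plasma draw within
#' `pairing_window_days`, then correlates (a) the per-locus MAFs pooled
#' over all paired timepoints and (b) the per-day mean MAF against the
#' SPD tumor burden.
#'
#' @inheritParams mean_maf
#' @param burden data frame with `day` and `spd_mm2` (days strictly
#'   increasing).
#' @param pairing_window_days admissible |imaging day - draw day| gap.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list `per_locus_r`, `mean_level_r`, `n_pairs`; correlations
#'   are `NA` with fewer than 3 pairs or zero variance.
#' @export
burden_concordance <- function(series, burden, panel_loci,
                               pairing_window_days = 14L, min_alt = 3L,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  draw_days <- sort(unique(series$day))
  pairs <- lapply(seq_len(nrow(burden)), function(i) {
    gap <- abs(draw_days - burden$day[i])
    if (min(gap) > pairing_window_days) return(NULL)
    d <- draw_days[order(gap, draw_days)][1]
    c(draw = d, spd = burden$spd_mm2[i])
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) < 3)
    return(list(per_locus_r = NA_real_, mean_level_r = NA_real_,
                n_pairs = if (is.null(pairs)) 0L else nrow(pairs)))
  locus_maf <- function(d) {
    s <- series[series$day == d, , drop = FALSE]
    maf <- ctdna_maf(s)
    maf[s$alt_reads < min_alt] <- 0
    full <- stats::setNames(numeric(length(panel_loci)), panel_loci)
    on_panel <- s$locus %in% panel_loci
    full[s$locus[on_panel]] <- maf[on_panel]
    full
  }
  per_locus_x <- unlist(lapply(pairs[, "draw"], locus_maf))
  per_locus_y <- rep(pairs[, "spd"], each = length(panel_loci))
  means <- vapply(pairs[, "draw"], mean_maf, numeric(1), series = series,
                  panel_loci = panel_loci, min_alt = min_alt)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }
  list(per_locus_r = safe_cor(per_locus_x, per_locus_y),
       mean_level_r = safe_cor(means, pairs[, "spd"]),
       n_pairs = nrow(pairs))
}

#' Paired comparison of event-detection times
#'
#' Two-tailed paired Student's t-test, e.g. of the day the 50% burden
#' decline is first seen in ctDNA versus on imaging, in patients where
#' both modalities reach it. Degenerate difference vectors are handled
#' explicitly: all-zero differences give `t = 0, p = 1`; a constant
#' nonzero difference has no within-pair variance, so the p-value is
#' reported as 0 with `degenerate = TRUE`.
#'
#' @param times_a,times_b equal-length paired day vectors (n >= 2).
#' @return list `mean_a`, `mean_b`, `t`, `df`, `p`, `degenerate`.
#' @export
paired_time_comparison <- function(times_a, times_b) {
  stopifnot(length(times_a) == length(times_b), length(times_a) >= 2)
  d <- times_a - times_b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(mean_a = mean(times_a), mean_b = mean(times_b),
                  t = 0, df = length(d) - 1L, p = 1, degenerate = TRUE))
    return(list(mean_a = mean(times_a), mean_b = mean(times_b),
                t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(times_a, times_b, paired = TRUE)
  list(mean_a = mean(times_a), mean_b = mean(times_b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}
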