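#' Kaplan-Meier curves and log-rank test by ctDNA response class
#'
#' Product-limit survival estimates per group and the log-rank
#' comparison, via the survival package. Groups whose records are all
#' censored have an undefined median (reported `NA`).
#'
#' @param pfs_days follow-up time in days from the first infusion.
#' @param event logical/0-1, progression or death observed.
#' @param group grouping vector (e.g. the week-8 ctDNA class).
#' @return list: `fit` (a `survfit`), `medians` (named vector),
#'   `chisq`, `df`, `p` (log-rank; `NA` with a single group).
#' @export
km_logrank <- function(pfs_days, event, group) {
  stopifnot(length(pfs_days) == length(event),
            length(pfs_days) == length(group), all(pfs_days >= 0))
  group <- droplevels(as.factor(group))
  df <- data.frame(time = pfs_days, event = as.integer(event),
                   group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) {
    medians <- stats::setNames(tab[["median"]], levels(group))
  } else {
    medians <- stats::setNames(tab[, "median"],
                               sub("^group=", "", rownames(tab)))
  }
  if (nlevels(group) < 2)
    return(list(fit = fit, medians = medians, chisq = NA_real_,
                df = 0L, p = NA_real_))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(sd$n) - 1
  list(fit = fit, medians = medians, chisq = unname(sd$chisq), df = dfree,
       p = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE))
}

#' Univariate Cox hazard ratio for the ctDNA response class
#'
#' Proportional-hazards estimate (Efron tie handling) with a Wald 95%
#' CI for the hazard of the non-reference class relative to
#' `reference`. When every event falls in one group the partial
#' likelihood is monotone (complete separation): the fit is flagged and
#' the CI reported as unbounded rather than silently trusted.
#'
#' @inheritParams km_logrank
#' @param reference level treated as the baseline hazard group.
#' @return list: `hr`, `ci_low`, `ci_high`, `loghr`, `se`, `p`,
#'   `n_events`, `separation` (logical flag).
#' @export
cox_hr <- function(pfs_days, event, group, reference = NULL) {
  group <- droplevels(as.factor(group))
  stopifnot(nlevels(group) == 2)
  if (!is.null(reference)) group <- stats::relevel(group, ref = reference)
  event <- as.integer(event)
  if (sum(event) < 1) stop("need at least one observed event")
  df <- data.frame(time = pfs_days, event = event, group = group)
  ev_by_group <- tapply(event, group, sum)
  separation <- any(ev_by_group == 0)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ group, data = df,
                    ties = "efron"))
  loghr <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  ci <- loghr + c(-1, 1) * stats::qnorm(0.975) * se
  list(hr = exp(loghr),
       ci_low = if (separation) 0 else exp(ci[1]),
       ci_high = if (separation) Inf else exp(ci[2]),
       loghr = loghr, se = se,
       p = 2 * stats::pnorm(-abs(loghr / se)),
       n_events = sum(event), separation = separation)
}

#' Order patients by ctDNA decline and test responder enrichment
#'
#' Stable ascending sort by fold-change (greatest ctDNA decline first);
#' missing fold-changes are placed last and flagged. Objective
#' responders (best response CR or PR) are tested for over-
#' representation in the top half of the ordering with a two-sided
#' Fisher exact test.
#'
#' @param patient_id,fold_change,best_response,tmb equal-length vectors;
#'   `best_response` in CR/PR/SD/PD; `tmb` optional annotation.
#' @return list: `table` (ordered data frame with `responder` and
#'   `missing_fc` flags), `fisher_p`, `odds_ratio`, `contingency`.
#' @export
response_ordering_report <- function(patient_id, fold_change,
                                     best_response, tmb = NA_real_) {
  n <- length(patient_id)
  tab <- data.frame(patient_id = patient_id, fold_change = fold_change,
                    best_response = best_response,
                    tmb = rep_len(tmb, n),
                    responder = best_response %in% c("CR", "PR"),
                    missing_fc = is.na(fold_change),
                    stringsAsFactors = FALSE)
  key <- tab$fold_change
  key[is.na(key)] <- Inf  # missing fold-changes sort last
  tab <- tab[order(key, method = "radix"), , drop = FALSE]  # stable
  rownames(tab) <- NULL
  top <- seq_len(n) <= n %/% 2
  cont <- table(top_half = factor(top, levels = c(TRUE, FALSE)),
                responder = factor(tab$responder,
                                   levels = c(TRUE, FALSE)))
  ft <- stats::fisher.test(cont)
  list(table = tab, fisher_p = ft$p.value,
       odds_ratio = unname(ft$estimate), contingency = cont)
}
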