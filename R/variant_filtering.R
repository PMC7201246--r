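#' Apply the somatic-variant retention rules
#'
#' Exclusion first: any variant inside a segmental duplication
#' (`in_superdup`) with VAF < `superdup_vaf_max`, or with a maximal
#' population frequency above `popfreq_cutoff`, is dropped regardless of
#' everything else. Retention second: nonsynonymous SNVs (and, by
#' design, small indels, which face the same allele-fraction bar but are
#' excluded from TMB) are kept when VAF > `vaf_min`, or when VAF >
#' `hotspot_vaf_min` at a flagged cancer hotspot. Synonymous variants
#' are never retained. Row order is preserved.
#'
#' @param variants data frame with at least `effect`, `vaf`,
#'   `popfreq_max`, `is_hotspot`, `in_superdup` (see
#'   [simulate_mutation_spectra()] for the full column set).
#' @param vaf_min VAF threshold for non-hotspot variants (exclusive).
#' @param hotspot_vaf_min VAF threshold at hotspots (exclusive).
#' @param superdup_vaf_max segmental-duplication exclusion VAF bound.
#' @param popfreq_cutoff maximal tolerated population frequency.
#' @param strict if `TRUE`, malformed rows (negative reads, VAF
#'   inconsistent with reads, missing fields) abort with the offending
#'   row indices; if `FALSE` they are skipped with a warning.
#' @param quiet suppress the per-rule drop-count message.
#' @return the retained subset, with an attribute `drop_counts` (named
#'   integer vector: `malformed`, `superdup`, `popfreq`, `effect`,
#'   `low_vaf`).
#' @export
filter_variants <- function(variants,
                            vaf_min = 0.03,
                            hotspot_vaf_min = 0.01,
                            superdup_vaf_max = 0.2,
                            popfreq_cutoff = 0.05,
                            strict = FALSE,
                            quiet = FALSE) {
  req <- c("effect", "vaf", "popfreq_max", "is_hotspot", "in_superdup")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  bad <- !is.finite(variants$vaf) | variants$vaf < 0 | variants$vaf > 1 |
    is.na(variants$effect)
  if (all(c("alt_reads", "total_reads") %in% names(variants))) {
    bad <- bad | variants$alt_reads < 0 |
      variants$alt_reads > variants$total_reads |
      abs(variants$vaf - variants$alt_reads / variants$total_reads) > 1e-6
  }
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    msg <- paste("malformed variant rows:",
                 paste(which(bad), collapse = ", "))
    if (strict) stop(msg) else warning(msg, "; rows skipped")
  }
  v <- variants[!bad, , drop = FALSE]

  excl_sd <- v$in_superdup & v$vaf < superdup_vaf_max
  excl_pf <- v$popfreq_max > popfreq_cutoff
  v1 <- v[!(excl_sd | excl_pf), , drop = FALSE]
  eff_ok <- v1$effect %in% c("nonsynonymous_snv", "indel")
  vaf_ok <- v1$vaf > vaf_min | (v1$is_hotspot & v1$vaf > hotspot_vaf_min)
  keep <- eff_ok & vaf_ok

  drops <- c(malformed = sum(bad),
             superdup = sum(excl_sd),
             popfreq = sum(excl_pf & !excl_sd),
             effect = sum(!eff_ok),
             low_vaf = sum(eff_ok & !vaf_ok))
  if (!quiet)
    message("filter_variants: retained ", sum(keep), "/", nrow(variants),
            " (dropped ", paste(names(drops), drops, sep = "=",
                                collapse = ", "), ")")
  out <- v1[keep, , drop = FALSE]
  attr(out, "drop_counts") <- drops
  out
}

#' Tumor mutational burden
#'
#' Nonsynonymous SNVs per megabase of coding sequence. Indels and
#' synonymous variants in the table are ignored.
#'
#' @param retained a (filtered) somatic-variant data frame.
#' @param coding_mb megabases of coding sequence interrogated by the
#'   assay; 38 Mb is a conventional whole-exome footprint.
#' @return mutations per Mb (numeric scalar).
#' @export
compute_tmb <- function(retained, coding_mb = 38) {
  if (!is.numeric(coding_mb) || length(coding_mb) != 1 || coding_mb <= 0)
    stop("coding_mb must be a positive number")
  sum(retained$effect == "nonsynonymous_snv") / coding_mb
}

#' Cancer cell fraction and clonality from binomial confidence intervals
#'
#' The cancer cell fraction (CCF) is the purity- and copy-number-
#' corrected allele fraction:
#' `CCF = VAF * (purity*tumor_cn + (1-purity)*normal_cn) /
#' (purity * multiplicity)`. The 95% CI of the VAF is the exact
#' Clopper-Pearson interval on `alt_reads / total_reads`, pushed through
#' the same affine map. A mutation is subclonal when the upper CCF bound
#' is below 1, clonal otherwise. Point estimates are deliberately not
#' capped at 1, so purity misspecification stays visible.
#'
#' All read-count arguments are vectorized.
#'
#' @param alt_reads,total_reads observed mutant and total read counts.
#' @param purity tumor purity in (0, 1].
#' @param tumor_cn,normal_cn local copy numbers in tumor and normal cells.
#' @param multiplicity number of mutated copies per tumor cell (>= 1).
#' @param conf_level confidence level of the interval.
#' @param strict if `TRUE`, zero alt reads abort ("undetected, clonality
#'   undefined"); otherwise such calls get label `NA`.
#' @return data frame with `ccf`, `ccf_low`, `ccf_high`, `label`
#'   (`"clonal"`/`"subclonal"`), plus the inputs `vaf`, `purity`,
#'   `tumor_cn`, `normal_cn`, `multiplicity`.
#' @export
call_clonality <- function(alt_reads, total_reads, purity = 1,
                           tumor_cn = 2, normal_cn = 2, multiplicity = 1,
                           conf_level = 0.95, strict = FALSE) {
  stopifnot(all(purity > 0), all(purity <= 1), all(total_reads > 0),
            all(multiplicity >= 1), all(alt_reads >= 0),
            all(alt_reads <= total_reads))
  if (strict && any(alt_reads == 0))
    stop("undetected, clonality undefined (alt_reads = 0 in strict mode)")
  n <- max(length(alt_reads), length(total_reads))
  alt_reads <- rep_len(alt_reads, n); total_reads <- rep_len(total_reads, n)
  purity <- rep_len(purity, n); tumor_cn <- rep_len(tumor_cn, n)
  normal_cn <- rep_len(normal_cn, n)
  multiplicity <- rep_len(multiplicity, n)

  vaf <- alt_reads / total_reads
  ci <- clopper_pearson(alt_reads, total_reads, conf_level)
  scale <- (purity * tumor_cn + (1 - purity) * normal_cn) /
    (purity * multiplicity)
  ccf <- vaf * scale
  ccf_low <- ci$lower * scale
  ccf_high <- ci$upper * scale
  label <- ifelse(ccf_high < 1, "subclonal", "clonal")
  label[alt_reads == 0] <- NA_character_
  data.frame(ccf = ccf, ccf_low = ccf_low, ccf_high = ccf_high,
             label = label, vaf = vaf, purity = purity,
             tumor_cn = tumor_cn, normal_cn = normal_cn,
             multiplicity = multiplicity, stringsAsFactors = FALSE)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact two-sided binomial interval; the
#' lower bound is 0 at zero successes and the upper bound 1 at full
#' successes. Vectorized over `x` and `n`.
#'
#' @param x successes; @param n trials; @param conf_level level.
#' @return list with vectors `lower` and `upper`.
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  lower <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  list(lower = lower, upper = upper)
}
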