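#' Retain strong MHC binders
#'
#' Keeps neoepitope candidates with predicted IC50 strictly below the
#' affinity threshold (default 500 nM, the conventional cutoff for a
#' peptide deemed a binder), ordered by `rank_score` ascending (stable:
#' ties keep input order).
#'
#' @param candidates neoepitope-candidate data frame (`variant_ref`,
#'   `ic50_nm`, `rank_score`, ...).
#' @param threshold_nm positive affinity cutoff in nM.
#' @return the filtered, rank-ordered subset (possibly empty).
#' @export
filter_binders <- function(candidates, threshold_nm = 500) {
  if (!is.numeric(threshold_nm) || threshold_nm <= 0)
    stop("threshold_nm must be positive")
  keep <- candidates[candidates$ic50_nm < threshold_nm, , drop = FALSE]
  keep[order(keep$rank_score), , drop = FALSE]
}

#' Design an individually customized panel (ICP)
#'
#' Collapses binding epitopes to unique coding variants (a variant keeps
#' its best, i.e. lowest, `rank_score` over its epitopes), then:
#'
#' * with at least `min_loci` unique neoantigen variants, the top
#'   `min(n, max_loci)` by rank become the panel (all `neoantigen`);
#' * with fewer, every neoantigen variant is taken and the remaining
#'   slots up to `min_loci` are filled with the highest-VAF variants not
#'   yet on the panel (`vaf_filler`), stopping early only if the variant
#'   table is exhausted.
#'
#' Ordering is deterministic: rank ascending, ties broken by higher VAF,
#' then lexicographically by (chrom, pos, ref, alt); fillers by VAF
#' descending with the same lexicographic fallback.
#'
#' @param binders output of [filter_binders()] (may be empty).
#' @param all_variants the patient's retained somatic-variant table.
#' @param patient_id identifier stored on the design.
#' @param min_loci,max_loci panel size bounds (defaults 20 and 30).
#' @return object of class `panel_design`: list with `patient_id`,
#'   `loci` (data frame: `locus` key, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `vaf`, `rank_score`, `source`) and `coverage_fraction`
#'   (NA until [coverage_fraction()] is computed).
#' @export
design_panel <- function(binders, all_variants, patient_id = "P",
                         min_loci = 20L, max_loci = 30L) {
  if (is.null(all_variants) || nrow(all_variants) == 0)
    stop("all_variants must be nonempty")
  av <- all_variants
  av$locus <- variant_key(av$chrom, av$pos, av$ref, av$alt)

  neo <- data.frame(locus = character(), rank_score = numeric())
  if (!is.null(binders) && nrow(binders) > 0) {
    rs <- tapply(binders$rank_score, binders$variant_ref, min)
    neo <- data.frame(locus = names(rs), rank_score = as.numeric(rs),
                      stringsAsFactors = FALSE)
  }
  if (!all(neo$locus %in% av$locus))
    stop("binders reference variants absent from all_variants")
  neo <- merge(neo, av[, c("locus", "chrom", "pos", "ref", "alt",
                           "gene", "vaf")], by = "locus", sort = FALSE)
  neo <- neo[order(neo$rank_score, -neo$vaf, neo$chrom, neo$pos,
                   neo$ref, neo$alt), , drop = FALSE]

  if (nrow(neo) >= min_loci) {
    sel <- utils::head(neo, max_loci)
    sel$source <- "neoantigen"
  } else {
    sel <- neo
    if (nrow(sel)) sel$source <- "neoantigen" else sel$source <- character()
    pool <- av[!(av$locus %in% sel$locus), , drop = FALSE]
    pool <- pool[order(-pool$vaf, pool$chrom, pool$pos, pool$ref,
                       pool$alt), , drop = FALSE]
    need <- min_loci - nrow(sel)
    if (need > 0 && nrow(pool) > 0) {
      fill <- utils::head(pool, need)
      fill <- data.frame(locus = fill$locus, rank_score = NA_real_,
                         chrom = fill$chrom, pos = fill$pos,
                         ref = fill$ref, alt = fill$alt, gene = fill$gene,
                         vaf = fill$vaf, source = "vaf_filler",
                         stringsAsFactors = FALSE)
      sel <- rbind(sel[, names(fill)], fill)
    }
  }
  rownames(sel) <- NULL
  cols <- c("locus", "chrom", "pos", "ref", "alt", "gene", "vaf",
            "rank_score", "source")
  structure(list(patient_id = patient_id,
                 loci = sel[, cols, drop = FALSE],
                 coverage_fraction = NA_real_),
            class = "panel_design")
}

#' Fraction of predicted neoepitopes covered by the panel
#'
#' The fraction of predicted epitopes whose coding variant sits on the
#' panel; epitope-level, so a multi-epitope variant counts once per
#' epitope.
#'
#' @param panel a `panel_design` object.
#' @param predicted nonempty neoepitope-candidate data frame.
#' @return a proportion in \[0, 1\].
#' @export
coverage_fraction <- function(panel, predicted) {
  stopifnot(inherits(panel, "panel_design"))
  if (is.null(predicted) || nrow(predicted) == 0)
    stop("predicted candidate table must be nonempty")
  mean(predicted$variant_ref %in% panel$loci$locus)
}

#' @export
print.panel_design <- function(x, ...) {
  src <- table(x$loci$source)
  cat("ICP panel for ", x$patient_id, ": ", nrow(x$loci), " loci (",
      paste(names(src), src, sep = "=", collapse = ", "), ")",
      if (!is.na(x$coverage_fraction))
        sprintf("; neoepitope coverage %.1f%%", 100 * x$coverage_fraction),
      "\n", sep = "")
  invisible(x)
}

#' Write a panel as BED intervals plus a TSV manifest
#'
#' BED uses 0-based half-open coordinates; each locus becomes an
#' interval of `2*flank + 1` bases centered on the variant position.
#'
#' @param panel a `panel_design` object.
#' @param bed_path,manifest_path output file paths (NULL to skip one).
#' @param flank bases added on each side of the locus.
#' @return invisibly, the paths written.
#' @export
write_panel <- function(panel, bed_path = NULL, manifest_path = NULL,
                        flank = 60L) {
  stopifnot(inherits(panel, "panel_design"))
  loci <- panel$loci
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = loci$chrom,
                      start = pmax(0L, loci$pos - 1L - flank),
                      end = loci$pos + flank,
                      name = paste(panel$patient_id, loci$locus, sep = "|"))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(manifest_path)) {
    man <- cbind(patient_id = panel$patient_id, loci)
    utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(bed = bed_path, manifest = manifest_path))
}
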