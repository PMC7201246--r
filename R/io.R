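# Tabular I/O for the documented flat formats. Variant tables are TSV,
# time courses CSV; all coordinates are 1-based (VCF convention).

#' Read / write a somatic-variant table (TSV)
#'
#' Columns: `patient_id`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `effect`, `alt_reads`, `total_reads`, `vaf`, `popfreq_max`,
#' `is_hotspot`, `in_superdup`.
#'
#' @param path file path.
#' @return `read_variant_table`: a named list of per-patient data
#'   frames.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$is_hotspot <- as.logical(df$is_hotspot)
  df$in_superdup <- as.logical(df$in_superdup)
  split(df[setdiff(names(df), "patient_id")], df$patient_id)
}

#' @rdname read_variant_table
#' @param spectra named list of per-patient variant data frames.
#' @export
write_variant_table <- function(spectra, path) {
  df <- do.call(rbind, Map(function(id, v) cbind(patient_id = id, v),
                           names(spectra), spectra))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Emit mutation spectra as minimal VCF 4.2
#'
#' One record per variant with INFO keys `GENE`, `EFFECT`, `PF`
#' (maximal population frequency), `HOTSPOT`, `SUPERDUP` and a single
#' sample column carrying `AD` (ref,alt depths). Indels are emitted
#' as-is with their stored alleles.
#'
#' @param variants one patient's variant data frame.
#' @param path output path; @param sample_id sample column name.
#' @export
write_variants_vcf <- function(variants, path, sample_id = "TUMOR") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
    "##INFO=<ID=PF,Number=1,Type=Float,Description=\"Max population frequency\">",
    "##INFO=<ID=HOTSPOT,Number=0,Type=Flag,Description=\"Cancer hotspot\">",
    "##INFO=<ID=SUPERDUP,Number=0,Type=Flag,Description=\"Segmental duplication\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")), con)
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  info <- sprintf("GENE=%s;EFFECT=%s;PF=%g%s%s", v$gene, v$effect,
                  v$popfreq_max,
                  ifelse(v$is_hotspot, ";HOTSPOT", ""),
                  ifelse(v$in_superdup, ";SUPERDUP", ""))
  ad <- sprintf("%d,%d", v$total_reads - v$alt_reads, v$alt_reads)
  writeLines(paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                   info, "AD", ad, sep = "\t"), con)
  invisible(path)
}

#' Read / write ctDNA time courses (long CSV)
#'
#' Columns `patient_id`, `locus`, `day`, `alt_reads`, `depth`
#' (and `maf`, recomputed on read).
#'
#' @param path file path.
#' @return named list of per-patient series data frames.
#' @export
read_ctdna_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$maf <- df$alt_reads / df$depth
  split(df[setdiff(names(df), "patient_id")], df$patient_id)
}

#' @rdname read_ctdna_csv
#' @param series named list or single long data frame with `patient_id`.
#' @export
write_ctdna_csv <- function(series, path) {
  df <- if (is.data.frame(series)) series else
    do.call(rbind, c(series, list(make.row.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write tumor-burden and outcome tables (CSV)
#' @param path file path.
#' @return named list of per-patient burden data frames
#'   (`read_burden_csv`) or one outcome data frame (`read_outcomes_csv`).
#' @export
read_burden_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split(df[setdiff(names(df), "patient_id")], df$patient_id)
}

#' @rdname read_burden_csv
#' @param burden named list or long data frame with `patient_id`.
#' @export
write_burden_csv <- function(burden, path) {
  df <- if (is.data.frame(burden)) burden else
    do.call(rbind, c(burden, list(make.row.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_burden_csv
#' @export
read_outcomes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$event <- as.logical(df$event)
  df
}

#' Read a gene panel (one symbol per line, or two-column TSV whose
#' second column is the symbol)
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_gene_panel <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) {
    unique(utils::read.delim(path, header = FALSE,
                             stringsAsFactors = FALSE)[[2]])
  } else {
    unique(trimws(readLines(path)))
  }
}
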