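# In-code fixture builders shared across test files.

# a well-formed random somatic-variant table; VAFs exactly consistent
# with reads (total fixed at 1000 so boundary VAFs are representable)
random_variant_table <- function(n, vaf_pool = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vaf <- if (is.null(vaf_pool)) round(runif(n, 0, 0.6), 3)
         else sample(vaf_pool, n, replace = TRUE)
  total <- rep(1000L, n)
  alt <- as.integer(round(vaf * total))
  data.frame(
    chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
    pos = sample.int(1e8, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    gene = sprintf("G%04d", sample.int(5000, n, replace = TRUE)),
    effect = sample(c("nonsynonymous_snv", "synonymous_snv", "indel"),
                    n, replace = TRUE, prob = c(0.7, 0.15, 0.15)),
    alt_reads = alt, total_reads = total, vaf = alt / total,
    popfreq_max = sample(c(0, 0.01, 0.04, 0.06, 0.2), n, replace = TRUE,
                         prob = c(0.6, 0.15, 0.1, 0.1, 0.05)),
    is_hotspot = runif(n) < 0.3,
    in_superdup = runif(n) < 0.2,
    stringsAsFactors = FALSE)
}

# distinct variants plus an epitope table referencing a subset of them
random_panel_instance <- function(n_variants, n_binder_variants,
                                  epitopes_per = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- random_variant_table(n_variants)
  v <- v[!duplicated(variant_keys(v)), , drop = FALSE]
  nb <- min(n_binder_variants, nrow(v))
  cand <- NULL
  if (nb > 0) {
    pick <- sample(nrow(v), nb)
    rows <- rep(pick, each = epitopes_per)
    cand <- data.frame(
      variant_ref = variant_keys(v)[rows],
      gene = v$gene[rows],
      peptide = replicate(length(rows), paste(
        sample(LETTERS[1:20], 9, replace = TRUE), collapse = "")),
      hla_allele = "HLA-A*02:01",
      ic50_nm = runif(length(rows), 1, 499),
      stringsAsFactors = FALSE)
    cand$rank_score <- cand$ic50_nm
  }
  list(variants = v, binders = cand)
}

variant_keys <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

# a small ctDNA series data frame from a locus x day MAF matrix
series_from_matrix <- function(maf, days, depth = 1000L) {
  loci <- rownames(maf)
  data.frame(
    locus = rep(loci, times = ncol(maf)),
    day = rep(days, each = nrow(maf)),
    alt_reads = as.integer(round(as.vector(maf) * depth)),
    depth = depth,
    stringsAsFactors = FALSE)
}
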