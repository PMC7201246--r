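#' Pairwise mutation-spectrum overlap
#'
#' Percentage overlap of two mutated-gene sets, the Jaccard index in
#' percent: `100 * |a intersect b| / |a union b|`.
#'
#' @param a,b character vectors of gene symbols (duplicates ignored);
#'   both empty is an error.
#' @return a percentage in \[0, 100\].
#' @export
overlap_percentage <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stop("overlap of two empty gene sets is undefined")
  100 * length(intersect(a, b)) / u
}

#' Cohort-wide pairwise overlap summary
#'
#' Evaluates [overlap_percentage()] for every unordered patient pair
#' and summarizes the distribution.
#'
#' @param spectra named list (patient -> character vector of mutated
#'   genes); at least two patients.
#' @return list with `matrix` (symmetric, 100 on the diagonal),
#'   `pairs` (data frame `a`, `b`, `overlap_pct`) and `summary`
#'   (median, lower and upper quartile of the pairwise values).
#' @export
cohort_overlap_summary <- function(spectra) {
  if (length(spectra) < 2) stop("need at least 2 patients")
  ids <- names(spectra)
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  pairs <- list()
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ov <- overlap_percentage(spectra[[i]], spectra[[j]])
      m[i, j] <- m[j, i] <- ov
      k <- k + 1L
      pairs[[k]] <- data.frame(a = ids[i], b = ids[j], overlap_pct = ov,
                               stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  q <- stats::quantile(pairs$overlap_pct, c(0.25, 0.5, 0.75), names = FALSE)
  list(matrix = m, pairs = pairs,
       summary = c(median = q[2], q1 = q[1], q3 = q[3]))
}

# round half-up to `digits` decimals (report parity; R's round() is
# round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Shared-gene percentages from raw counts
#'
#' @param n_shared genes shared by at least k patients (any k).
#' @param union_size total number of distinct mutated genes.
#' @return percentage, rounded half-up to 2 decimals.
#' @export
shared_gene_percentage <- function(n_shared, union_size) {
  if (union_size <= 0) stop("union_size must be positive")
  round_half_up(100 * n_shared / union_size, 2)
}

#' Gene recurrence across a cohort
#'
#' Counts how many distinct genes are mutated cohort-wide, how many
#' recur in at least two patients, and how many in more than three
#' (i.e. at least four) patients, with the corresponding percentages of
#' the mutated-gene union (2 decimals, half-up).
#'
#' @param spectra named list of per-patient mutated-gene sets (>= 2).
#' @param min_shared patients needed to count as "shared" (default 2).
#' @param min_recurrent patients needed to count as highly recurrent
#'   (default 4, the literal reading of "more than three").
#' @return list: `union_size`, `n_shared_ge2`, `n_shared_gt3`,
#'   `pct_ge2`, `pct_gt3`, and `gene_counts` (named patient counts).
#' @export
recurrence_stats <- function(spectra, min_shared = 2L, min_recurrent = 4L) {
  if (length(spectra) < 2) stop("need at least 2 patients")
  counts <- table(unlist(lapply(spectra, unique), use.names = FALSE))
  union_size <- length(counts)
  if (union_size == 0) stop("empty cohort spectrum")
  n_ge2 <- sum(counts >= min_shared)
  n_gt3 <- sum(counts >= min_recurrent)
  list(union_size = union_size,
       n_shared_ge2 = n_ge2, n_shared_gt3 = n_gt3,
       pct_ge2 = shared_gene_percentage(n_ge2, union_size),
       pct_gt3 = shared_gene_percentage(n_gt3, union_size),
       gene_counts = counts)
}

#' Overlap counts between a gene panel and each patient's spectrum
#'
#' @param panel_genes character vector of the panel's gene symbols.
#' @param spectra named list of per-patient mutated-gene sets.
#' @return named integer vector: per-patient `|panel ∩ spectrum|`.
#' @export
panel_spectrum_overlap <- function(panel_genes, spectra) {
  stopifnot(length(panel_genes) > 0, length(spectra) > 0)
  panel_genes <- unique(panel_genes)
  vapply(spectra, function(g) length(intersect(panel_genes, unique(g))),
         integer(1))
}

#' Compare panels' per-patient overlap counts
#'
#' Omnibus Kruskal-Wallis test across the panel groups followed by
#' Dunn's pairwise post-hoc z-tests (tie-corrected) with
#' Benjamini-Hochberg adjustment — the standard workflow for comparing
#' a personalized panel against fixed commercial panels on count data
#' with heavy ties.
#'
#' When every observation across every group is identical there is no
#' rank information at all; that degenerate case is reported as H = 0,
#' p = 1 (and all pairwise z = 0).
#'
#' @param count_groups named list (panel -> numeric vector of
#'   per-patient overlap counts), >= 2 groups of >= 2 values.
#' @return list with `kw_h`, `kw_p`, `pairwise` (data frame: `group1`,
#'   `group2`, `z`, `p`, `p_adj`).
#' @export
compare_panels <- function(count_groups) {
  if (length(count_groups) < 2) stop("need at least 2 groups")
  if (any(lengths(count_groups) < 2)) stop("each group needs >= 2 values")
  x <- unlist(count_groups, use.names = FALSE)
  g <- factor(rep(names(count_groups), times = lengths(count_groups)),
              levels = names(count_groups))
  if (length(unique(x)) == 1L) {
    cmb <- utils::combn(names(count_groups), 2)
    pairwise <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                           z = 0, p = 1, p_adj = 1,
                           stringsAsFactors = FALSE)
    return(list(kw_h = 0, kw_p = 1, pairwise = pairwise))
  }
  kw <- stats::kruskal.test(x, g)
  pairwise <- dunn_test(x, g)
  pairwise$p_adj <- stats::p.adjust(pairwise$p, method = "BH")
  list(kw_h = unname(kw$statistic), kw_p = kw$p.value, pairwise = pairwise)
}

#' Dunn's post-hoc test (tie-corrected)
#'
#' Pairwise z statistics on mean pooled ranks after a Kruskal-Wallis
#' test: `z = (Rbar_i - Rbar_j) / se` with
#' `se^2 = (N(N+1)/12 - T/(12(N-1))) * (1/n_i + 1/n_j)` and
#' `T = sum(t^3 - t)` over tie groups. Two-sided normal p-values,
#' unadjusted (see [compare_panels()] for BH adjustment).
#'
#' @param x pooled observations; @param g grouping factor.
#' @return data frame `group1`, `group2`, `z`, `p`.
#' @export
dunn_test <- function(x, g) {
  g <- droplevels(as.factor(g))
  r <- rank(x)
  N <- length(x)
  tie <- table(x)
  tie_term <- sum(tie^3 - tie)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  lev <- levels(g)
  cmb <- utils::combn(lev, 2)
  z <- numeric(ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term / (12 * (N - 1))) *
                 (1 / ns[[i]] + 1 / ns[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
  }
  data.frame(group1 = cmb[1, ], group2 = cmb[2, ], z = z,
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}
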