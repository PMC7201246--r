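---
title: "Methods: personalized-panel ctDNA monitoring with icptrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized-panel ctDNA monitoring with icptrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icptrack)
```

## The problem

Non-small cell lung cancer shows extreme inter-patient heterogeneity in
its somatic mutation spectrum: across large exome cohorts the median
Jaccard overlap between any two patients' mutated-gene sets is on the
order of 1–2%, and only a handful of genes (TP53, TTN, MUC16, ...) recur
in more than half of a cohort. Fixed commercial liquid-biopsy panels
therefore cover only a small slice of any individual tumor's mutations.
`icptrack` implements the alternative: an *individually customized
panel* (ICP) of 20–30 loci chosen from each patient's own predicted
neoantigen-coding mutations, used to follow circulating tumor DNA
(ctDNA) during checkpoint-blockade therapy, and the downstream kinetics
and survival analyses that make that signal clinically interpretable.

## Variant retention, TMB and clonality

Input variants arrive annotated (gene, coding effect, read support,
maximal population frequency, hotspot and segmental-duplication flags).
Retention follows two stages, applied in `filter_variants()`:

1. **Exclusion.** Variants inside `genomicSuperDups` segmental
   duplications with VAF < 0.2, or with a maximal population frequency
   above 0.05, are removed outright (likely mapping artifacts or
   germline polymorphisms).
2. **Retention.** Nonsynonymous SNVs are kept when VAF > 3%, or VAF > 1%
   at a flagged cancer hotspot. Small indels face the same
   allele-fraction bar but are excluded from TMB, whose definition
   (`compute_tmb()`) counts nonsynonymous SNVs per megabase of coding
   sequence (default footprint 38 Mb). Hotspot membership is an input
   flag, not an internal catalogue: published hotspot lists differ, and
   the flag keeps the rule auditable.

The cancer cell fraction of each mutation is the purity- and
copy-number-corrected allele fraction

$$\mathrm{CCF} = \mathrm{VAF}\cdot
  \frac{p\,C_T + (1-p)\,C_N}{p\,m},$$

with purity $p$, tumor/normal local copy numbers $C_T, C_N$, and
mutation multiplicity $m$. Defaults $p=1$, $C_T=C_N=2$, $m=1$ give the
diploid shorthand $\mathrm{CCF} = 2\,\mathrm{VAF}$; all four parameters
are overridable per variant. The 95% CI of the VAF is the exact
Clopper–Pearson (beta-quantile) interval on `alt_reads / total_reads`,
pushed through the same affine map; a mutation is **subclonal** when the
upper CCF bound is below 1, clonal otherwise. Two deliberate choices:

* CCF point estimates are *not* capped at 1 — capping would mask purity
  misspecification, while the clonality rule only consults the CI bound.
* At the boundary itself (true CCF exactly 1) any two-sided 95% interval
  places ~2.5% of its error mass below the truth, so a truly clonal
  mutation is mislabeled subclonal in roughly 2% of deep-sequencing
  replicates. This is a property of 95% confidence, not of the
  implementation; the calibration tests assert the attainable bound.

## Panel design

`filter_binders()` keeps peptide–HLA candidates with predicted IC50
strictly below 500 nM, the conventional binder cutoff.
`design_panel()` then collapses epitopes to unique coding variants (a
variant keeps its best, i.e. lowest, IC50-scale rank), and:

* with ≥ 20 unique binder variants, takes the top `min(n, 30)` by rank —
  the text's "top 20–30" is read as a 30-cap with no trimming down to
  20;
* with fewer, takes all of them and pads with the highest-VAF remaining
  variants to 20 loci (stopping early only when the variant table is
  exhausted).

Ties are broken by higher VAF, then lexicographically by
(chrom, pos, ref, alt), so panels are bit-reproducible. Panels are
gene/variant-level; `rank_score` defaults to the IC50 itself because it
is the only stated affinity scale, and an alternative percentile-rank
column is accepted. `coverage_fraction()` reports the fraction of the
predicted dominant-neoepitope repertoire whose coding variant made the
panel.

## Cohort heterogeneity statistics

`overlap_percentage()` is the Jaccard index in percent;
`recurrence_stats()` counts genes shared by ≥ 2 and by > 3 patients
("more than three" is read literally as ≥ 4, configurable) and reports
percentages of the mutated-gene union rounded *half-up* to two decimals
for parity with published tables. Panel-versus-spectrum comparisons use
per-patient overlapping-gene counts (gene counts, following the
convention of plotting "number of overlapping genes") compared across
panels by a Kruskal–Wallis omnibus test, Dunn's tie-corrected post-hoc
z-tests, and Benjamini–Hochberg adjustment. Dunn's statistic is
implemented in the package (tie-corrected pooled-rank variance) and is
verified against from-scratch rank arithmetic in the tests; the
degenerate all-identical case is defined as H = 0, p = 1 rather than
left to a 0/0.

## ctDNA kinetics

A panel locus is **detected** in a draw when it carries ≥ 3 mutant reads
(configurable; plasma callers differ and the study's limit of detection
is not published). The per-day summary is the arithmetic mean MAF over
*all* panel loci with undetected loci contributing zero — this makes the
statistic a panel-level tumor-content proxy rather than a
detected-only average (a `detected_only` mode is provided). Key derived
quantities:

* `fold_change()` — mean MAF at the draw nearest to day 7×week (window
  ±14 days, ties to the earlier draw) over baseline; undefined when the
  baseline is zero, and such patients are excluded from cohort summaries
  with a recorded reason.
* `classify_response()` — a ≥ 50% decline at week 8 (fold-change ≤ 0.5,
  boundary inclusive) defines the ctDNA responder class.
* `time_to_half()` — first linear-interpolated crossing of half the
  baseline, in days; "not reached" is `NA`.
* `burden_concordance()` — imaging timepoints (SPD, the sum of products
  of perpendicular lesion diameters) are paired to the nearest plasma
  draw within ±14 days; Pearson correlation (Spearman optional) is
  reported per-locus pooled and at the mean level.
* `paired_time_comparison()` — two-tailed paired t-test of
  ctDNA-detected versus imaging-detected times to the 50% decline;
  constant nonzero differences have no within-pair variance and are
  reported as |t| → ∞, p = 0 with a degeneracy flag instead of a
  misleading finite value.

## Outcomes

Kaplan–Meier estimation, log-rank comparison and the univariate Cox
model (Efron ties) come from the `survival` package behind
`km_logrank()` and `cox_hr()`. PFS is measured from the first infusion.
With cohort sizes around ten, complete separation (all events in one
ctDNA class) is a real possibility; the Cox wrapper detects it, flags
monotone likelihood, and reports an unbounded CI rather than a silently
diverged estimate. `response_ordering_report()` sorts patients by
fold-change (stable sort; missing values last and flagged) and tests
objective-responder enrichment in the top half with a two-sided Fisher
exact test.

## The synthetic cohort generator

No patient-level data are distributed with studies of this kind, so
`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes. What it emulates, and the defaults chosen once as
study conditions:

* **Mutation spectra.** Each patient draws 38–496 mutations (uniform),
  genes sampled without replacement from a 12,000-gene pool under a
  truncated power law (rank$^{-\alpha}$, $\alpha = 0.4$). These values
  reproduce a cohort median pairwise overlap of ~1–2% (IQR roughly
  0.6–2) with a few TP53/TTN-like recurrent genes — the heterogeneity
  regime the panel-design argument rests on. True VAFs are
  Beta(2, 8) (right-skewed, mean 0.2, as in impure clinical specimens);
  reads are binomial at ~500× tissue depth.
* **Neoepitopes.** Nonsynonymous variants yield Poisson(0.22)
  peptide–HLA candidates with IC50 log-uniform on [10 nM, 50 µM], giving
  ~28 dominant (< 500 nM) neoantigens per patient at the default
  mutation load, matching reported repertoire sizes.
* **Plasma signal.** Baseline locus MAF = tissue VAF × a log-normal
  shedding factor (meanlog log 0.1, sdlog 2) with 5% of loci never shed;
  observed reads are binomial at 2000×. This yields baseline/ever
  detection medians near 80%/90%. There is no UMI or sequencing-error
  model: noise is pure binomial sampling.
* **Trajectories.** Five scenarios couple a tumor-burden multiplier to
  the ctDNA multiplier: exponential response (≤ 0.5× burden by day 56),
  stable disease, exponential progression, a resistant clone whose
  panel signal decays linearly to zero by day 84 while the tumor grows
  (neoantigen loss — the panel goes dark in the face of progression),
  and an occult relapse whose ctDNA re-rises from day 239 to 14× baseline
  by day 351 while imaged burden stays low. Plasma draws default to days
  0/28/56/84 then six-weekly; imaging is six-weekly (42 days), the
  standard response-evaluation cadence. The exact plasma cadence is not
  published for such protocols (~monthly draws are implied by sample
  counts), so it is configurable.
* **Outcomes.** PFS is scenario-dependent exponential (means 400/160/70/
  70/290 days) with administrative censoring at 540 days, since
  per-patient survival times are never published.

What the generator does **not** model — and what passing tests therefore
do not establish about real data: clonal copy-number structure, purity
drift between draws, sequencing error and UMI consensus artifacts,
lesion-level RECIST bookkeeping, pseudo-progression, and any biological
lag between tumor-cell kill and imaged shrinkage (the simulated ctDNA
lead over imaging arises purely from denser sampling and the convexity
of exponential decay under linear interpolation, and is accordingly
small; clinically reported leads are much larger).

## Numerical choices and problem sizes

Determinism is a contract: every generator accepts a seed, cohort
simulation derives per-stage substreams from it, and the pipeline
manifest (config hash + row counts) is byte-identical across repeated
runs. Degenerate inputs are defined, not accidental: empty binder sets
fall through to VAF-filler panels; zero baseline MAF flags the patient
out of fold-change summaries; all-identical rank data short-circuits the
Kruskal–Wallis path; zero-variance series report `NA` correlations.
Validation-scale simulations in the test-suite use cohorts of 200
patients at 10,000× plasma depth for classification/concordance
recovery, 1000 replicates per depth for CI calibration, and 100
replicates of 500-per-arm exponential survival for Cox recovery — sizes
at which Monte-Carlo error is comfortably below the asserted margins.

## Known limitations

The binder threshold treats IC50 as the only affinity scale; percentile
ranks are accepted but not converted. The CCF model assumes a single
multiplicity per variant and takes purity as given. Mean-MAF
zero-imputation ties the summary to panel size when loci drop out for
technical rather than biological reasons. And the generator's scenario
taxonomy is a deliberate caricature: real trajectories mix scenario
features, so classification accuracy on simulated cohorts is an upper
bound, not a clinical performance estimate.
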