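Package: icptrack
Title: Personalized Neoantigen Panel Design and Circulating Tumor DNA
    Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for liquid-biopsy monitoring of cancer patients with
    individually customized sequencing panels (ICPs). Implements somatic
    variant retention rules, tumor mutational burden, cancer cell fraction
    and clonality calls from exact binomial confidence intervals,
    neoantigen-guided panel construction (top binders supplemented with
    high-VAF loci), cohort mutation-spectrum heterogeneity statistics
    (pairwise Jaccard overlap, gene recurrence, panel comparisons with
    Kruskal-Wallis and Dunn post-hoc tests), longitudinal ctDNA kinetics
    (detection rates, mean mutant allele fraction, week-8 response
    classification, time to 50 percent decline, tumor-burden concordance),
    and survival association of the ctDNA response class (Kaplan-Meier,
    log-rank, Cox). A synthetic-cohort generator reproduces the
    statistical structure of such studies so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
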