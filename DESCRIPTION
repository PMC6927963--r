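Package: aeikit
Title: Allelic Expression Imbalance Analysis and Censored Cold-Pain Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying allelic expression imbalance (AEI) at
    heterozygous marker SNPs from targeted amplicon sequencing, with a
    genomic-DNA control for amplification bias, genotype calling from
    pyrosequencing traces and TaqMan Cq pairs, two-site haplotype phasing
    from clone-end Sanger observations, and linkage of a regulatory risk
    allele to the lower-expressed haplotype. Also implements the
    statistical endpoints of a cold-pain quantitative sensory testing
    cohort: within-subject averaging of censored repeats, Kaplan-Meier and
    Cox time-to-event analysis with fixed right-censoring, Kruskal-Wallis
    with conditional Dunn-Sidak post-hoc comparisons, baseline-adjusted
    repeated-measures mixed models for blood pressure, and two-sample
    t-test power. A synthetic-data module generates every input the
    pipeline consumes so all stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    emmeans,
    lmerTest,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
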