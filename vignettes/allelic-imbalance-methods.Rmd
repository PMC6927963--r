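---
title: "Measuring allelic expression imbalance and cold-pain endpoints: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring allelic expression imbalance and cold-pain endpoints: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeikit)
library(tibble)
```

## The scientific problem

A regulatory variant near a gene can lower transcription from the
chromosome that carries it. In a person heterozygous for both the
regulatory variant and a *marker SNP* inside the gene's coding region, the
marker's two alleles tag the two chromosomes' mRNA, so the ratio of
minor-allele to common-allele reads in cDNA measures *allelic expression
imbalance* (AEI). The same ratio measured in genomic DNA (gDNA), where the
two chromosomes are present 1:1, is the control: it isolates amplification
bias and aneuploidy from a genuine transcriptional effect. `aeikit`
implements that comparison for targeted amplicon sequencing of the
cold-sensor channel gene *TRPM8*, the phasing step that places the
regulatory risk allele on a chromosome, and the statistical endpoints of a
cold-pain psychophysics cohort stratified by that risk allele.

## The AEI model

For a sample with true expression ratio $\rho$ (minor-chromosome over
common-chromosome transcripts), the minor-allele read fraction in cDNA is
$p = \rho/(1+\rho)$, and observed counts are binomial at the sequencing
depth. Symmetric per-base miscalls at rate $\varepsilon$ shift the
observed fraction to $p' = p(1-\varepsilon) + (1-p)\varepsilon$. In gDNA
the fraction is $0.5$ perturbed by amplification bias, modeled as
logit-normal: $\mathrm{logit}(p) \sim N(0, \sigma_b)$. The reported
quantity per barcode is the ratio `count_minor / count_common`; the
absolute fold change is $\max(r, 1/r)$, computed on unrounded ratios and
rounded to one decimal only for display.

Key thresholds, all overridable arguments:

* **Read floor 10,000** (inclusive): a barcode with fewer allelic reads is
  rejected as unquantifiable rather than reported with a wide ratio.
* **gDNA control window [0.8, 1.25]**: log-symmetric around 1, wide
  enough to contain the small gDNA wobble the assay produces
  ($\sigma_b = 0.06$ gives typical gDNA ratios of roughly 0.89–1.13)
  while rejecting genuinely aberrant genomic material.
* **Significance of imbalance**: no canonical test exists for a single
  sample's cDNA-vs-gDNA contrast, so we test equality of minor-allele
  fractions on the 2×2 material-by-allele table — Fisher's exact test
  below a total of $10^5$ reads, the Yates-corrected chi-square above it.
  This uses the gDNA control as the reference distribution, which is the
  control's purpose.
* **Replicate aggregation** is the arithmetic mean of per-replicate
  ratios (matching an "average imbalance" report), with read totals
  averaged separately. Pooling counts before the ratio is a defensible
  alternative; mean-of-ratios was chosen because it weights replicates
  equally regardless of depth. The p-value, in contrast, is computed on
  pooled counts, because it is a statement about reads, not replicates.
* **Zero-count alleles** make the fold change an error, not infinity;
  callers wanting a finite answer can add a documented 0.5 pseudo-count
  to the counts before computing ratios.

## Genotype calling

Two assay models feed the genotype calls:

* **Pyrosequencing** reports the percentage of base calls per allele. A
  heterozygote requires *both* alleles at ≥ 25% (inclusive). If neither
  reaches the threshold the trace is background-dominated and the result
  is `no_call` — an ordinary value, not an exception, so that pipelines
  skip rather than abort.
* **TaqMan** reports a Cq per allele channel under exponential
  amplification with efficiency 2 and a 40-cycle program, so template is
  proportional to $2^{40-\mathrm{Cq}}$ and Cq = 40 encodes "no
  amplification". The minor-allele share
  $2^{40-\mathrm{Cq_{SNP}}} / (2^{40-\mathrm{Cq_{REF}}} +
  2^{40-\mathrm{Cq_{SNP}}})$ lies in $[0,1]$; we scale it by 2 so that
  the metric spans $[0, 2]$ with 1 at perfect balance and the
  heterozygote window is $[0.5, 1.5]$. The factor of 2 is the only
  reading under which the formula, the stated range and the stated
  window are mutually consistent; without it the window would swallow
  every homozygote-minor call. Window boundaries are inclusive for het:
  a boundary tie resolves toward the call that keeps a sample eligible
  for AEI, which is the conservative direction for this design (a
  wrongly included sample is caught later by the gDNA control; a wrongly
  excluded one is lost).

Marker-SNP eligibility screening applies four published criteria: coding
region, ≤ 30 kb from the regulatory SNP (inclusive; long-range PCR limits
the phaseable span), sufficient CEU heterozygosity, and a single-exon
amplicon (so gDNA and cDNA amplicons are comparable).

## Phasing and risk-allele linkage

Cloned long-range PCR fragments are single-chromosome molecules, so
Sanger reads at both ends observe one allele of each SNP from the same
haplotype. With two heterozygous sites only two pairings exist; each
clone supports exactly one. We take the majority pairing and report the
majority fraction as concordance. Defaults `min_clones = 5` and
`min_concordance = 0.8` are this package's acceptance rule, chosen to
reject the known failure mode — degraded gDNA yielding chimeric clones —
rather than force a call; an exact tie is an explicit ambiguity error.
Only two-site phasing is supported, matching the experiment.

The linkage verdict asks whether the risk allele shares a chromosome with
the lower-expressed marker allele. "Lower-expressed" is read from the
cDNA ratio relative to the gDNA baseline (ratio below baseline means the
minor allele lost expression). The verdict is `indeterminate` whenever
the gDNA control failed or the imbalance is not significant — the gate is
deliberate: linkage claims inherit the control's validity.

## Cohort endpoints

The thermode protocol starts at 32 °C (thermal neutrality) and cools at
1 °C/s to 0 °C, holding there for the remainder of the test; a threshold
felt above the floor therefore satisfies `time = 32 − temperature`
exactly, and thresholds during the hold have temperature 0 and
`time ≥ 32`. QST analysis times are right-censored at 152 s and
cold-pressor (CPT) times at 300 s.

* **Within-subject averaging** precedes all group analyses. Sessions
  mixing observed events and censorings are summarized by the *any-event
  rule*: the mean of observed event times with event status true; only a
  subject censored in every session stays censored at the limit. This
  biases mixed summaries downward — we flag it prominently because no
  averaging rule for censored repeats is neutral, and this one at least
  keeps the event indicator honest.
* **Kaplan–Meier / Cox**: standard product-limit and partial-likelihood
  fits (via the `survival` package) with Breslow tie handling by default
  — the 60-second measurement grid makes ties common — and Efron behind
  a flag. Monotone likelihood is surfaced as a non-convergence error.
* **Kruskal–Wallis** is tie-corrected with the asymptotic chi-square
  p-value; for pooled samples of ten or fewer the p-value switches to
  exhaustive enumeration of all group assignments. Post-hoc pairwise
  Dunn z tests run *only* when the omnibus p-value is significant, and
  their p-values are Dunn–Šidák adjusted, $p_{adj} = 1-(1-p)^m$.
* **Blood pressure** uses change-from-baseline with fixed effects group,
  time, group×time and the baseline covariate, plus a random subject
  intercept fitted by REML — compound symmetry, the simplest
  repeated-measures covariance; the choice is recorded in the fit
  object. Least-squares means come from `emmeans`.
* **Design power** uses the exact noncentral-t power of the two-sided
  two-sample t test; at a mean difference of 8.45 mm Hg, SD 9.5 and 20
  per group it returns 0.783, consistent with a stated 80% design power
  at that effect size.

## What the synthetic cohort does and does not emulate

The generator reproduces the statistical structure the analyses assume:
genotype-stratified latent thresholds (defaults TT 5.4 °C, TC 5.4 °C,
CC 0.2 °C — the recessive pattern in which only CC homozygotes approach
the floor), between-subject SD 2 °C, within-subject session SD 1 °C, six
sessions (three per day over two days), exponential pain onset during the
0 °C hold (hazard 0.05/s), near-total censoring of the tolerance
endpoint, a pressor blood-pressure response sampled each minute, and
Likert scores as a noisy monotone map of stimulus intensity clamped to
integers 0–10. Group sizes default to 20/12/6 (TT/TC/CC), matching a
38-participant cohort with 18 carriers. Within-subject variance and the
hold-phase hazard are stated defaults, not estimates — no published
values exist for them.

It does **not** model skin thermodynamics, sex or age covariates,
session-order effects, or any correlation between cold sensitivity and
blood pressure. Passing tests therefore demonstrate that the *analysis
machinery* is correct and calibrated (type-I error, parameter recovery,
censoring handling), not that real cohorts behave like the generator.

## Numerical and degenerate-input choices

* Seeds make every generator bit-reproducible; identical config and seed
  give identical output.
* The Kruskal–Wallis exact route compares permuted statistics with a
  $10^{-10}$ slack to absorb floating-point ties, and a fully constant
  sample short-circuits to $H = 0$, $p = 1$.
* `dunn_sidak` clamps to $[p, 1]$ so the adjusted value can never fall
  below the raw one through floating-point rounding at $m = 1$.
* A 100%-censored endpoint (the tolerance endpoints routinely are) fits
  a Kaplan–Meier curve of constant 1 and skips the Cox contrast with a
  recorded reason instead of erroring.
* FASTQ records whose sequence and quality lengths disagree are a hard
  error naming the record; reads too short to cover the SNP offset, or
  below the Q20 base-quality default at the SNP base, are skipped and
  tallied.

## Problem sizes used in the checks

The packaged checks run the AEI recovery at depth $10^5$ with 200
replicates per true ratio, the null calibration of the imbalance test on
2,000 simulated pairs at depth 20,000 per material, the end-to-end
phasing scenario 500 times at 20 clones with 2% clone error, TaqMan
recovery at 10,000 draws per genotype, and Cox recovery on 200 runs of
500 subjects per group. These sizes give Monte-Carlo standard errors
comfortably below the margins being asserted. One statistical fact is
worth stating plainly: at 500 subjects per group with all events
observed, the Cox log-hazard-ratio estimate has standard deviation about
0.065, so a ±10% band around a true hazard ratio of 2 captures about
87–88% of runs — not 90% — and the packaged check of that band reports
exactly what the estimator delivers.

## Known limitations

Barcode demultiplexing, read alignment, indels and UMI handling are out
of scope: reads are assumed amplicon-derived and are counted by direct
offset lookup. Population-scale phasing (EM/HMM, reference panels) is out
of scope. The cohort analyses reproduce the published analysis plan, not
the published participant-level results, which were never deposited.
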