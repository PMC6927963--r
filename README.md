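# aeikit

Quantifying allelic expression imbalance (AEI) from targeted amplicon
sequencing, and analyzing censored cold-pain endpoints in a
genotype-stratified cohort.

## The problem

When a regulatory variant reduces transcription from the chromosome that
carries it, a heterozygous coding-region *marker SNP* inside the gene tags
the two chromosomes' mRNA. The minor/common allele read-count ratio in
cDNA then measures imbalance directly, and the same ratio in genomic DNA
(gDNA) — where the chromosomes are 1:1 — controls for amplification bias
and aneuploidy. `aeikit` implements this design end to end for the
cold-sensor gene *TRPM8* and its migraine-associated regulatory variants:

* **genotyping** — pyrosequencing calls (both alleles ≥ 25% → het) and
  TaqMan Cq calls via the metric
  `2 · 2^(40−Cq_SNP) / (2^(40−Cq_REF) + 2^(40−Cq_SNP)) ∈ [0, 2]`,
  heterozygous in `[0.5, 1.5]`; marker-SNP eligibility screening
  (coding region, ≤ 30 kb from the regulatory SNP, CEU heterozygosity,
  single-exon amplicon);
* **counting** — per-allele counts at the amplicon SNP offset from FASTQ
  (Phred+33, Q20 base-quality default), with a hard 10,000-read floor
  per barcode;
* **AEI** — ratio `r = minor/common`, absolute fold change
  `max(r, 1/r)`, gDNA control window `[0.8, 1.25]`, and a
  Fisher/chi-square test of the cDNA-vs-gDNA allele fractions;
* **phasing** — majority-vote two-site phasing from clone-end Sanger
  observations, then linkage of the risk allele to the lower-expressed
  haplotype (`risk_on_low` / `risk_on_high` / `indeterminate`);
* **cohort statistics** — within-subject averaging of repeated QST/CPT
  sessions, Kaplan–Meier and Cox fits with right-censoring at 152 s
  (QST) / 300 s (CPT), tie-corrected Kruskal–Wallis with exact
  enumeration for small samples, conditional Dunn–Šidák post-hoc
  comparisons (`p_adj = 1 − (1 − p)^m`), a baseline-adjusted
  repeated-measures mixed model for blood pressure, and noncentral-t
  power for the two-sample design;
* **synthetic data** — generators for every input above (binomial allele
  counts with gDNA logit-normal bias, FASTQ reads, Cq pairs, pyro
  traces, clone observations, and a full thermode-protocol cohort), so
  the whole pipeline is testable with no external data.

## Worked example

Three synthetic heterozygous samples with true expression ratios 0.57,
0.41 and 0.95, sequenced at depth 20,000 with two replicates per
material, phased from 20 clones each:

```r
library(aeikit)
library(tibble)

samples <- tibble(sample_id = c("DRG01", "DRG02", "DRG03"),
                  snp_id = "rs_marker", rho = c(0.57, 0.41, 0.95))
cfg <- aei_sim_config(samples, depth = 2e4, replicates = 2, seed = 42)
haps <- list(c(rmr = "C", marker = "A"), c(rmr = "T", marker = "G"))
clones <- setNames(lapply(1:3, function(i)
  simulate_clone_reads(haps, 20, 0.02, seed = 100 + i)), samples$sample_id)
markers <- tibble(sample_id = samples$sample_id, risk_allele = "C",
                  marker_common = "G", marker_minor = "A")

run <- run_aei_pipeline(sim_config = cfg, clones = clones, markers = markers)
render_aei_table(run$report)
#>   sample_id snp_id    gdna_ratio cdna_ratio fold_change gdna_control_pass
#> 1 DRG01     rs_marker       1.05       0.57         1.8 TRUE
#> 2 DRG02     rs_marker       1.12       0.42         2.4 TRUE
#> 3 DRG03     rs_marker       0.95       0.94         1.1 TRUE
run$verdicts
#>   sample_id concordance verdict
#> 1 DRG01               1 risk_on_low
#> 2 DRG02               1 risk_on_low
#> 3 DRG03               1 indeterminate
```

The first two samples recover their true ratios (0.57, 0.41 up to
binomial noise), pass the gDNA control, and the risk allele lands on the
lower-expressed haplotype. The third sample's ratio 0.94 is
indistinguishable from its gDNA baseline, so its linkage verdict is
correctly `indeterminate` rather than a forced call.

The cohort side, on a simulated 38-subject cohort (TT/TC/CC = 20/12/6)
with the default latent thresholds 5.4/5.4/0.2 °C:

```r
co <- simulate_cohort(cohort_sim_config(seed = 7))
run <- run_cohort_pipeline(co)
run$temperature$genotype$omnibus$p_value
#> [1] 0.0006172217
run$temperature$genotype$dunn
#>   comparison       z    p_raw    p_adj
#> 1 CC vs TC   -3.37   0.000739 0.00222
#> 2 CC vs TT   -3.70   0.000214 0.000641
#> 3 TC vs TT   -0.0986 0.921    1.000
```

The omnibus Kruskal–Wallis test on recorded threshold temperatures is
significant, which gates in the pairwise Dunn comparisons; both CC
contrasts survive the Šidák adjustment while TC vs TT does not — the
recessive pattern the generator encodes. Design power at a mean systolic
difference of 8.45 mm Hg (SD 9.5, n = 20/group):

```r
ttest_power(8.45, 9.5, 20)
#> [1] 0.7826249
```

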