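#' Screen candidate marker SNPs for AEI eligibility
#'
#' A marker SNP (mSNP) is usable as a transcript-level tag only if it (i)
#' lies in the gene's coding region, (ii) sits within `max_distance_bp`
#' (default 30 kb) of the regulatory risk SNP so the pair remains amenable
#' to long-range PCR phasing, (iii) is sufficiently heterozygous in the
#' reference (CEU) population, and (iv) can be amplified from cDNA with an
#' amplicon falling inside a single exon.
#'
#' @param candidates Tibble with columns `snp_id`, `in_coding_region`
#'   (logical), `distance_to_rmr_bp`, `ceu_heterozygosity` (in `[0, 0.5]`),
#'   `single_exon_amplicon` (logical).
#' @param max_distance_bp Maximum distance to the risk SNP (inclusive).
#' @param min_ceu_het Minimum CEU heterozygosity (inclusive).
#' @return The retained candidates, with an attribute `rejections`: a
#'   tibble of rejected `snp_id`s and their failure reasons.
#' @export
select_marker_snps <- function(candidates, max_distance_bp = 30000,
                               min_ceu_het = 0.3) {
  req <- c("snp_id", "in_coding_region", "distance_to_rmr_bp",
           "ceu_heterozygosity", "single_exon_amplicon")
  missing <- setdiff(req, names(candidates))
  if (length(missing) > 0) {
    stop("candidates missing column(s): ", paste(missing, collapse = ", "))
  }
  reasons <- purrr::pmap(candidates[req], function(snp_id, in_coding_region,
                                                   distance_to_rmr_bp,
                                                   ceu_heterozygosity,
                                                   single_exon_amplicon) {
    r <- character(0)
    if (!in_coding_region) r <- c(r, "not in coding region")
    if (distance_to_rmr_bp > max_distance_bp) {
      r <- c(r, sprintf("distance %d bp exceeds %d bp", distance_to_rmr_bp,
                        as.integer(max_distance_bp)))
    }
    if (ceu_heterozygosity < min_ceu_het) {
      r <- c(r, sprintf("CEU heterozygosity %.3f below %.3f",
                        ceu_heterozygosity, min_ceu_het))
    }
    if (!single_exon_amplicon) r <- c(r, "amplicon spans exon boundary")
    r
  })
  keep <- lengths(reasons) == 0
  rejections <- tibble::tibble(
    snp_id = candidates$snp_id[!keep],
    reason = vapply(reasons[!keep], paste, "", collapse = "; ")
  )
  out <- candidates[keep, ]
  attr(out, "rejections") <- rejections
  out
}

#' Call a genotype from a pyrosequencing trace
#'
#' Heterozygous calls require both alleles present at `het_threshold_pct`
#' percent or greater (inclusive). Otherwise the call is homozygous for
#' the allele with the larger percentage; when both percentages fall below
#' the threshold (background-dominated trace) the result is `no_call`,
#' which downstream stages must skip.
#'
#' @param trace One-row tibble (or list) with `snp_id`, `common_pct`,
#'   `minor_pct`, percentages in `[0, 100]`.
#' @param het_threshold_pct Heterozygote threshold, default 25.
#' @param sample_id Identifier for the output.
#' @return One-row tibble: `sample_id`, `snp_id`, `call`, `metric` (the
#'   minor-allele percentage), `method = "pyro"`.
#' @export
call_pyro_genotype <- function(trace, het_threshold_pct = 25,
                               sample_id = "S1") {
  common <- trace$common_pct
  minor <- trace$minor_pct
  if (common < 0 || minor < 0 || common > 100 || minor > 100) {
    stop("percentages must lie in [0, 100]")
  }
  call <- if (common >= het_threshold_pct && minor >= het_threshold_pct) {
    "het"
  } else if (common < het_threshold_pct && minor < het_threshold_pct) {
    "no_call"
  } else if (common >= minor) "hom_common" else "hom_minor"
  tibble::tibble(sample_id = sample_id, snp_id = trace$snp_id,
                 call = call, metric = minor, method = "pyro")
}

#' TaqMan allelic-discrimination metric
#'
#' Converts a Cq pair into a dimensionless allele-balance value in
#' `[0, 2]`: 0 means only the reference (common) allele amplified, 2 only
#' the minor allele, and 1 perfectly balanced amplification
#' (heterozygote). The amplification model is exponential with efficiency
#' 2, so a template amount is proportional to `2^(40 - Cq)` with 40 cycles
#' the program length (a Cq of 40 encodes no amplification). The minor
#' fraction `2^(40-cq_snp) / (2^(40-cq_ref) + 2^(40-cq_snp))` is scaled by
#' 2 so the stated range `[0, 2]` and the heterozygote window `[0.5, 1.5]`
#' of [call_taqman_genotype()] are mutually consistent.
#'
#' @param cq_ref,cq_snp Quantification cycles of the reference-allele and
#'   minor-allele channels, each in `(0, 40]`.
#' @return Numeric metric in `[0, 2]`.
#' @export
taqman_metric <- function(cq_ref, cq_snp) {
  if (any(cq_ref <= 0 | cq_ref > 40) || any(cq_snp <= 0 | cq_snp > 40)) {
    stop("Cq values must lie in (0, 40]")
  }
  a_ref <- 2^(40 - cq_ref)
  a_snp <- 2^(40 - cq_snp)
  2 * a_snp / (a_ref + a_snp)
}

#' Call a genotype from the TaqMan metric
#'
#' Heterozygous iff the metric lies in the closed window `[0.5, 1.5]`
#' (boundaries resolve toward het, the conservative call when selecting
#' samples for allele-specific expression); below 0.5 is homozygous
#' common, above 1.5 homozygous minor.
#'
#' @param metric Value from [taqman_metric()], in `[0, 2]`.
#' @param sample_id,snp_id Identifiers for the output.
#' @return One-row tibble: `sample_id`, `snp_id`, `call`, `metric`,
#'   `method = "taqman"`.
#' @export
call_taqman_genotype <- function(metric, sample_id = "S1", snp_id = "snp") {
  if (any(metric < 0 | metric > 2)) stop("metric must lie in [0, 2]")
  call <- ifelse(metric < 0.5, "hom_common",
                 ifelse(metric > 1.5, "hom_minor", "het"))
  tibble::tibble(sample_id = sample_id, snp_id = snp_id, call = call,
                 metric = metric, method = "taqman")
}
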