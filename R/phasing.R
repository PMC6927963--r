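#' Phase two heterozygous sites from clone-end observations
#'
#' Each cloned long-range PCR fragment derives from a single chromosome,
#' so Sanger reads at its two ends observe one allele of the risk SNP and
#' one allele of the marker SNP from the same haplotype. With two alleles
#' at each site there are only two possible pairings; the one consistent
#' with the majority of clones is returned, with the majority fraction as
#' concordance. An exact tie is an ambiguous-phasing error, and a
#' concordance below `min_concordance` (e.g. from degraded gDNA producing
#' chimeric clones) is a phasing failure rather than a forced call.
#'
#' @param observations Tibble with columns `clone_id`, `allele_rmr`,
#'   `allele_marker`.
#' @param min_concordance Minimum majority fraction to accept a phase.
#' @param min_clones Minimum number of clones required.
#' @return A list of class `haplotype_pair`: `haplotype_a` and
#'   `haplotype_b` (each a named character vector with elements `rmr` and
#'   `marker`), `concordance` and `n_clones`.
#' @export
phase_haplotypes <- function(observations, min_concordance = 0.8,
                             min_clones = 5) {
  n <- nrow(observations)
  if (n < min_clones) {
    stop("insufficient clones: ", n, " < ", min_clones)
  }
  r_alleles <- sort(unique(observations$allele_rmr))
  m_alleles <- sort(unique(observations$allele_marker))
  if (length(r_alleles) != 2 || length(m_alleles) != 2) {
    stop("sample must be heterozygous at both sites (two alleles each); ",
         "observed ", length(r_alleles), " risk-SNP and ",
         length(m_alleles), " marker alleles")
  }
  # pairing 1: r1-m1 / r2-m2 ; pairing 2: r1-m2 / r2-m1
  support1 <- sum(
    (observations$allele_rmr == r_alleles[1] &
       observations$allele_marker == m_alleles[1]) |
      (observations$allele_rmr == r_alleles[2] &
         observations$allele_marker == m_alleles[2])
  )
  support2 <- n - support1
  if (support1 == support2) {
    stop("ambiguous phasing: the two pairings are supported by equally ",
         "many clones (", support1, " each)")
  }
  if (support1 > support2) {
    hap_a <- c(rmr = r_alleles[1], marker = m_alleles[1])
    hap_b <- c(rmr = r_alleles[2], marker = m_alleles[2])
    concordance <- support1 / n
  } else {
    hap_a <- c(rmr = r_alleles[1], marker = m_alleles[2])
    hap_b <- c(rmr = r_alleles[2], marker = m_alleles[1])
    concordance <- support2 / n
  }
  if (concordance < min_concordance) {
    stop(sprintf("phasing concordance %.3f below acceptance threshold %.3f",
                 concordance, min_concordance))
  }
  structure(list(haplotype_a = hap_a, haplotype_b = hap_b,
                 concordance = concordance, n_clones = n),
            class = "haplotype_pair")
}

#' Link the risk allele to the lower-expressed haplotype
#'
#' Decides whether the regulatory risk allele sits on the chromosome whose
#' transcripts are under-represented. The lower-expressed marker allele is
#' read off the imbalance result: the cDNA ratio (minor/common) relative
#' to the gDNA baseline identifies which allele lost expression. The
#' verdict is `indeterminate` when the gDNA control failed or the
#' imbalance is not significant at `alpha`.
#'
#' @param pair A [phase_haplotypes()] result.
#' @param result One row of an [aei_report()] for the phased marker.
#' @param risk_allele Risk allele base at the regulatory SNP (e.g. "C").
#' @param marker_common,marker_minor Common and minor allele bases of the
#'   marker SNP.
#' @param alpha Significance level for the imbalance test.
#' @return One of `"risk_on_low"`, `"risk_on_high"`, `"indeterminate"`.
#' @export
link_risk_allele <- function(pair, result, risk_allele, marker_common,
                             marker_minor, alpha = 0.05) {
  stopifnot(inherits(pair, "haplotype_pair"))
  haps <- list(pair$haplotype_a, pair$haplotype_b)
  marker_alleles <- vapply(haps, function(h) h[["marker"]], "")
  if (!all(sort(marker_alleles) == sort(c(marker_common, marker_minor)))) {
    stop("marker is not heterozygous for the stated alleles in the pair")
  }
  rmr_alleles <- vapply(haps, function(h) h[["rmr"]], "")
  if (!(risk_allele %in% rmr_alleles)) {
    stop("risk allele '", risk_allele, "' absent from the phased pair")
  }
  if (isFALSE(result$gdna_control_pass) || is.na(result$p_value) ||
      result$p_value >= alpha) {
    return("indeterminate")
  }
  # relative expression of the minor allele, with the gDNA ratio as baseline
  rel <- result$cdna_ratio / result$gdna_ratio
  low_allele <- if (rel < 1) marker_minor else marker_common
  risk_hap <- haps[[which(rmr_alleles == risk_allele)]]
  if (risk_hap[["marker"]] == low_allele) "risk_on_low" else "risk_on_high"
}
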