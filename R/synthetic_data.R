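#' Simulation configuration for allelic-imbalance sequencing
#'
#' Bundles everything needed to generate per-allele read counts for a set of
#' samples in both materials (gDNA and cDNA). The central quantity is `rho`,
#' the true cDNA expression ratio: minor-chromosome transcripts divided by
#' common-chromosome transcripts. In cDNA the minor-allele read fraction is
#' `rho / (1 + rho)`; in gDNA the two chromosomes are present 1:1 and the
#' fraction is 0.5 up to amplification bias.
#'
#' @param samples Data frame with columns `sample_id`, `snp_id` and `rho`
#'   (true expression ratio, > 0), one row per sample by marker.
#' @param depth Sequencing depth per material and replicate (reads, >= 1).
#' @param error_rate Per-base probability that a read reports the other
#'   allele, in `[0, 0.25)`. Errors are modeled as symmetric allele flips.
#' @param gdna_bias_sd Standard deviation, on the logit scale, of the
#'   per-replicate gDNA amplification bias around a 0.5 allele fraction.
#'   The default 0.06 makes typical gDNA ratios span roughly 0.89-1.13.
#' @param replicates Replicates per material (>= 1).
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return An object of class `aei_sim_config`.
#' @export
aei_sim_config <- function(samples, depth = 1e5, error_rate = 0,
                           gdna_bias_sd = 0.06, replicates = 2, seed = 1L) {
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "snp_id", "rho")
  missing <- setdiff(req, names(samples))
  if (length(missing) > 0) {
    stop("`samples` is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(samples$rho <= 0)) stop("all `rho` must be > 0")
  if (depth < 1) stop("`depth` must be >= 1")
  if (error_rate < 0 || error_rate >= 0.25) {
    stop("`error_rate` must lie in [0, 0.25)")
  }
  if (gdna_bias_sd < 0) stop("`gdna_bias_sd` must be >= 0")
  if (replicates < 1) stop("`replicates` must be >= 1")
  structure(
    list(samples = samples, depth = as.integer(depth),
         error_rate = error_rate, gdna_bias_sd = gdna_bias_sd,
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "aei_sim_config"
  )
}

#' Simulate per-allele amplicon read counts
#'
#' For each sample, material and replicate the minor-allele count is drawn
#' as Binomial(depth, p') where `p = rho / (1 + rho)` for cDNA,
#' `p = plogis(bias)` with `bias ~ Normal(0, gdna_bias_sd)` for gDNA, and
#' `p' = p (1 - e) + (1 - p) e` folds in the symmetric sequencing-error
#' rate `e`. The common-allele count is `depth - minor`; no third-allele
#' reads are generated (errors flip between the two alleles).
#'
#' @param config An [aei_sim_config()].
#' @return Tibble of allele counts with columns `sample_id`, `snp_id`,
#'   `material` ("gDNA"/"cDNA"), `replicate`, `count_common`,
#'   `count_minor`, `count_other`.
#' @export
simulate_allele_counts <- function(config) {
  stopifnot(inherits(config, "aei_sim_config"))
  set.seed(config$seed)
  e <- config$error_rate
  rows <- list()
  for (i in seq_len(nrow(config$samples))) {
    s <- config$samples[i, ]
    for (material in c("gDNA", "cDNA")) {
      for (rep_i in seq_len(config$replicates)) {
        p <- if (material == "cDNA") {
          s$rho / (1 + s$rho)
        } else {
          stats::plogis(stats::rnorm(1, 0, config$gdna_bias_sd))
        }
        p_obs <- p * (1 - e) + (1 - p) * e
        minor <- stats::rbinom(1, config$depth, p_obs)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = s$sample_id, snp_id = s$snp_id, material = material,
          replicate = rep_i, count_common = config$depth - minor,
          count_minor = minor, count_other = 0L
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Amplicon specification
#'
#' Describes a sequenced amplicon carrying one biallelic SNP: the reference
#' sequence (which carries the common allele), the 0-based offset of the
#' SNP within it, and the two alleles.
#'
#' @param name Amplicon name.
#' @param reference Uppercase DNA string (A/C/G/T).
#' @param snp_offset 0-based index of the SNP in `reference`.
#' @param common_allele,minor_allele Distinct single bases; the reference
#'   base at `snp_offset` must equal `common_allele`.
#' @return An object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(name, reference, snp_offset, common_allele,
                          minor_allele) {
  reference <- toupper(reference)
  bases <- c("A", "C", "G", "T")
  if (!grepl("^[ACGT]+$", reference)) stop("reference must be A/C/G/T only")
  n <- nchar(reference)
  if (snp_offset < 0 || snp_offset >= n) {
    stop("`snp_offset` must satisfy 0 <= snp_offset < ", n)
  }
  if (!(common_allele %in% bases) || !(minor_allele %in% bases) ||
      common_allele == minor_allele) {
    stop("alleles must be distinct single bases in {A,C,G,T}")
  }
  ref_base <- substr(reference, snp_offset + 1, snp_offset + 1)
  if (ref_base != common_allele) {
    stop("reference base at snp_offset (", ref_base,
         ") must equal common_allele (", common_allele, ")")
  }
  structure(
    list(name = name, reference = reference,
         snp_offset = as.integer(snp_offset),
         common_allele = common_allele, minor_allele = minor_allele),
    class = "amplicon_spec"
  )
}

#' Simulate amplicon FASTQ reads
#'
#' Each read is the full amplicon reference with the base at the SNP offset
#' set to the minor allele with probability `minor_fraction`, after which
#' independent per-base substitution errors are applied at `error_rate`
#' (uniform over the three alternative bases). Qualities are constant
#' Phred+33 at `base_quality`.
#'
#' @param amplicon An [amplicon_spec()].
#' @param minor_fraction Probability a read carries the minor allele, in
#'   `[0, 1]`.
#' @param depth Number of reads.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param path Optional file path; when given, the reads are also written
#'   as a FASTQ file.
#' @param base_quality Constant Phred quality (default 37).
#' @return A [Biostrings::QualityScaledDNAStringSet] with an attribute
#'   `n_minor_assigned`: the number of reads whose SNP base was set to the
#'   minor allele before errors (the generator's own bookkeeping).
#' @export
simulate_fastq <- function(amplicon, minor_fraction, depth, error_rate = 0,
                           seed = 1L, path = NULL, base_quality = 37L) {
  stopifnot(inherits(amplicon, "amplicon_spec"))
  if (minor_fraction < 0 || minor_fraction > 1) {
    stop("`minor_fraction` must lie in [0, 1]")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- strsplit(amplicon$reference, "")[[1]]
  len <- length(ref)
  is_minor <- stats::runif(depth) < minor_fraction
  mat <- matrix(rep(ref, depth), nrow = depth, byrow = TRUE)
  mat[is_minor, amplicon$snp_offset + 1] <- amplicon$minor_allele
  if (error_rate > 0) {
    err <- matrix(stats::runif(depth * len) < error_rate, nrow = depth)
    idx <- which(err)
    if (length(idx) > 0) {
      # draw a base different from the current one
      cur <- mat[idx]
      alt <- vapply(cur, function(b) sample(setdiff(bases, b), 1), "")
      mat[idx] <- alt
    }
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- sprintf("read_%d", seq_len(depth))
  qual <- Biostrings::PhredQuality(
    rep(paste(rep(rawToChar(as.raw(base_quality + 33L)), len), collapse = ""),
        depth)
  )
  out <- Biostrings::QualityScaledDNAStringSet(reads, qual)
  if (!is.null(path)) {
    Biostrings::writeQualityScaledXStringSet(out, path)
  }
  attr(out, "n_minor_assigned") <- sum(is_minor)
  out
}

#' Simulate a TaqMan Cq pair for a known genotype
#'
#' Heterozygotes amplify both channels at the same cycle (`cq_het` plus
#' Gaussian noise). Homozygotes amplify only the matching channel one cycle
#' earlier (twice the template); the absent allele's channel is reported at
#' the 40-cycle cap, the assay's "no amplification" convention.
#'
#' @param genotype One of "hom_common", "het", "hom_minor".
#' @param cq_het Heterozygote quantification cycle, in `(0, 40]`.
#' @param noise_sd Gaussian noise SD on the cycle scale.
#' @param seed Integer seed.
#' @param n Number of independent measurements to draw.
#' @param sample_id,snp_id Identifiers carried into the output.
#' @return Tibble with columns `sample_id`, `snp_id`, `cq_ref`, `cq_snp`.
#' @export
simulate_taqman <- function(genotype = c("hom_common", "het", "hom_minor"),
                            cq_het = 25, noise_sd = 0, seed = 1L, n = 1L,
                            sample_id = "S1", snp_id = "snp") {
  genotype <- match.arg(genotype)
  if (cq_het <= 0 || cq_het > 40) stop("`cq_het` must lie in (0, 40]")
  set.seed(seed)
  noise <- function() stats::rnorm(n, 0, noise_sd)
  cap <- function(x) pmin(pmax(x, .Machine$double.eps), 40)
  if (genotype == "het") {
    cq_ref <- cap(cq_het + noise())
    cq_snp <- cap(cq_het + noise())
  } else if (genotype == "hom_common") {
    cq_ref <- cap(cq_het - 1 + noise())
    cq_snp <- rep(40, n)
  } else {
    cq_ref <- rep(40, n)
    cq_snp <- cap(cq_het - 1 + noise())
  }
  tibble::tibble(sample_id = sample_id, snp_id = snp_id,
                 cq_ref = cq_ref, cq_snp = cq_snp)
}

#' Simulate a pyrosequencing allele-percentage trace
#'
#' Heterozygotes give roughly 50/50 allele percentages and homozygotes
#' 100/0; Gaussian noise is added per allele, negatives are clamped to
#' zero, and the pair is renormalized to sum to 100.
#'
#' @param genotype One of "hom_common", "het", "hom_minor".
#' @param noise_sd Noise SD in percentage points.
#' @param seed Integer seed.
#' @param n Number of traces.
#' @param snp_id Identifier carried into the output.
#' @return Tibble with columns `snp_id`, `common_pct`, `minor_pct`.
#' @export
simulate_pyro_trace <- function(genotype = c("hom_common", "het", "hom_minor"),
                                noise_sd = 0, seed = 1L, n = 1L,
                                snp_id = "snp") {
  genotype <- match.arg(genotype)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  set.seed(seed)
  base <- switch(genotype,
                 het = c(50, 50),
                 hom_common = c(100, 0),
                 hom_minor = c(0, 100))
  common <- pmax(base[1] + stats::rnorm(n, 0, noise_sd), 0)
  minor <- pmax(base[2] + stats::rnorm(n, 0, noise_sd), 0)
  total <- common + minor
  tibble::tibble(snp_id = snp_id,
                 common_pct = 100 * common / total,
                 minor_pct = 100 * minor / total)
}

#' Simulate clone-end Sanger observations of a two-site haplotype pair
#'
#' Each clone derives from one of the two chromosomes with equal
#' probability; each of the two observed alleles is independently flipped
#' to the alternative allele at its site with probability `error_rate`.
#'
#' @param haplotypes List of two character vectors, each with elements
#'   `rmr` (risk-SNP allele) and `marker` (marker-SNP allele). The two
#'   haplotypes must differ at both sites.
#' @param n_clones Number of clones (>= 1).
#' @param error_rate Per-site allele-flip probability.
#' @param seed Integer seed.
#' @return Tibble with columns `clone_id`, `allele_rmr`, `allele_marker`.
#' @export
simulate_clone_reads <- function(haplotypes, n_clones, error_rate = 0,
                                 seed = 1L) {
  if (length(haplotypes) != 2) stop("`haplotypes` must contain two haplotypes")
  h1 <- haplotypes[[1]]; h2 <- haplotypes[[2]]
  if (h1[["rmr"]] == h2[["rmr"]] || h1[["marker"]] == h2[["marker"]]) {
    stop("the two haplotypes must differ at both sites")
  }
  if (n_clones < 1) stop("`n_clones` must be >= 1")
  set.seed(seed)
  from_h1 <- stats::runif(n_clones) < 0.5
  rmr <- ifelse(from_h1, h1[["rmr"]], h2[["rmr"]])
  marker <- ifelse(from_h1, h1[["marker"]], h2[["marker"]])
  flip_r <- stats::runif(n_clones) < error_rate
  flip_m <- stats::runif(n_clones) < error_rate
  rmr <- ifelse(flip_r, ifelse(rmr == h1[["rmr"]], h2[["rmr"]], h1[["rmr"]]),
                rmr)
  marker <- ifelse(flip_m,
                   ifelse(marker == h1[["marker"]], h2[["marker"]],
                          h1[["marker"]]),
                   marker)
  tibble::tibble(clone_id = sprintf("clone_%d", seq_len(n_clones)),
                 allele_rmr = rmr, allele_marker = marker)
}

#' Cohort simulation configuration
#'
#' Parameters of the synthetic cold-pain cohort. Subjects carry a genotype
#' at the regulatory risk SNP (TT, TC or CC) and a latent cold-pain
#' threshold temperature drawn per group. The thermode protocol starts at
#' 32 degrees C (thermal neutrality) and cools at 1 degree C per second to
#' a 0 degree floor, so a threshold reached above the floor maps to
#' `time = 32 - temperature` exactly; pain onset during the 0-degree hold
#' follows an exponential waiting time. QST times are right-censored at
#' 152 s and cold-pressor (CPT) times at 300 s.
#'
#' @param n_tt,n_tc,n_cc Subjects per genotype group.
#' @param mean_tt,mean_tc,mean_cc Latent mean threshold temperature per
#'   group (degrees C, <= 32). Defaults follow the recessive pattern in
#'   which only CC homozygotes feel cold pain near the 0-degree floor.
#' @param between_sd Between-subject SD of the latent threshold (degrees C).
#' @param within_sd Within-subject, between-session SD (degrees C).
#' @param sessions Sessions per subject (>= 1).
#' @param hold_hazard Hazard (events/s) of pain onset once the thermode
#'   holds at 0 degrees C.
#' @param tol_offset Degrees C subtracted from the threshold latent to give
#'   the tolerance latent (tolerance is reached at much colder stimuli).
#' @param tol_hold_hazard Hold-phase hazard for the tolerance endpoint;
#'   small by default so tolerance is almost always censored.
#' @param cpt_scale Multiplier mapping the QST threshold time scale onto
#'   the CPT (ice-water) time scale.
#' @param qst_censor,cpt_censor Right-censor limits, fixed at 152 and 300 s.
#' @param bp_sys_mean,bp_sys_sd,bp_dia_mean,bp_dia_sd Baseline systolic and
#'   diastolic blood-pressure distributions (mm Hg).
#' @param pressor_sys,pressor_dia Pressor response during CPT (mm Hg added
#'   to baseline at minutes >= 1).
#' @param bp_carrier_effect Extra systolic pressor response in carriers
#'   (mm Hg); 0 by default (no group-level cardiovascular difference).
#' @param bp_noise_sd Measurement noise on each BP reading (mm Hg).
#' @param likert_noise_sd Noise on the 0-10 Likert pain score.
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_tt = 20L, n_tc = 12L, n_cc = 6L,
                              mean_tt = 5.4, mean_tc = 5.4, mean_cc = 0.2,
                              between_sd = 2, within_sd = 1, sessions = 6L,
                              hold_hazard = 0.05, tol_offset = 10,
                              tol_hold_hazard = 0.005, cpt_scale = 1.5,
                              qst_censor = 152, cpt_censor = 300,
                              bp_sys_mean = 110, bp_sys_sd = 8,
                              bp_dia_mean = 70, bp_dia_sd = 6,
                              pressor_sys = 12, pressor_dia = 8,
                              bp_carrier_effect = 0, bp_noise_sd = 4,
                              likert_noise_sd = 1, seed = 1L) {
  if (any(c(n_tt, n_tc, n_cc) < 0)) stop("group sizes must be >= 0")
  if (any(c(mean_tt, mean_tc, mean_cc) > 32)) {
    stop("group mean thresholds must be <= 32 degrees C")
  }
  if (between_sd < 0 || within_sd < 0) stop("SDs must be >= 0")
  if (sessions < 1) stop("`sessions` must be >= 1")
  if (hold_hazard <= 0 || tol_hold_hazard <= 0) {
    stop("hold hazards must be > 0")
  }
  if (qst_censor != 152 || cpt_censor != 300) {
    stop("censor times are fixed at 152 s (QST) and 300 s (CPT)")
  }
  structure(as.list(environment()), class = "cohort_sim_config")
}

#' Simulate a genotype-stratified cold-pain cohort
#'
#' Generates per-subject, per-session quantitative-sensory-testing (QST)
#' and cold-pressor-test (CPT) outcomes under the thermode protocol
#' described in [cohort_sim_config()], along with baseline blood pressure,
#' a per-CPT blood-pressure series sampled at 60-second intervals, and
#' integer 0-10 Likert pain scores.
#'
#' Protocol geometry is exact: whenever a recorded QST threshold
#' temperature is above 0, its event time is `32 - temperature`; a
#' temperature of 0 means the event happened during the hold, at time
#' `32 + Exponential(hold_hazard)`. All QST times are capped at 152 s and
#' all CPT times at 300 s, with censor flags set exactly when the cap is
#' hit.
#'
#' @param config A [cohort_sim_config()].
#' @return A list of class `aei_cohort` with tibbles `subjects`
#'   (subject_id, genotype, carrier, baseline BP), `sessions` (one row per
#'   subject by session with QST/CPT endpoint times, censor flags,
#'   temperatures and Likert scores) and `bp` (subject, session, minute,
#'   systolic, diastolic).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cfg <- config
  n_total <- cfg$n_tt + cfg$n_tc + cfg$n_cc
  if (n_total == 0) {
    return(structure(list(subjects = tibble::tibble(),
                          sessions = tibble::tibble(),
                          bp = tibble::tibble()),
                     class = "aei_cohort"))
  }
  set.seed(cfg$seed)
  genotype <- rep(c("TT", "TC", "CC"), c(cfg$n_tt, cfg$n_tc, cfg$n_cc))
  means <- c(TT = cfg$mean_tt, TC = cfg$mean_tc, CC = cfg$mean_cc)
  subjects <- tibble::tibble(
    subject_id = sprintf("P%03d", seq_len(n_total)),
    genotype = genotype,
    carrier = genotype %in% c("TC", "CC"),
    theta = stats::rnorm(n_total, means[genotype], cfg$between_sd),
    bp_sys_baseline = stats::rnorm(n_total, cfg$bp_sys_mean, cfg$bp_sys_sd),
    bp_dia_baseline = stats::rnorm(n_total, cfg$bp_dia_mean, cfg$bp_dia_sd)
  )

  # one QST endpoint realisation: latent session temperature -> (temp, time,
  # censored) under the cool-then-hold geometry with the given censor limit
  realise <- function(theta_s, hazard, censor) {
    n <- length(theta_s)
    temp <- pmin(pmax(theta_s, 0), 32)
    time <- ifelse(theta_s > 0, 32 - pmin(theta_s, 32),
                   32 + stats::rexp(n, hazard))
    censored <- time >= censor
    time <- pmin(time, censor)
    temp[censored] <- 0
    list(temp = temp, time = time, censored = censored)
  }

  grid <- tidyr::expand_grid(subject_id = subjects$subject_id,
                             session = seq_len(cfg$sessions))
  grid <- dplyr::left_join(grid, subjects[, c("subject_id", "theta")],
                           by = "subject_id")
  ns <- nrow(grid)
  theta_s <- grid$theta + stats::rnorm(ns, 0, cfg$within_sd)
  theta_tol <- theta_s - cfg$tol_offset

  thr <- realise(theta_s, cfg$hold_hazard, cfg$qst_censor)
  tol <- realise(theta_tol, cfg$tol_hold_hazard, cfg$qst_censor)

  # CPT: same latent ordering, stretched time scale, 300 s cap
  cpt_thr_time <- pmin(cfg$cpt_scale * (32 - pmin(theta_s, 32)) +
                         ifelse(theta_s <= 0,
                                stats::rexp(ns, cfg$hold_hazard), 0),
                       cfg$cpt_censor)
  cpt_thr_cens <- cpt_thr_time >= cfg$cpt_censor
  cpt_tol_time <- pmin(cfg$cpt_scale * (32 - pmin(theta_tol, 32)) +
                         ifelse(theta_tol <= 0,
                                stats::rexp(ns, cfg$tol_hold_hazard), 0),
                       cfg$cpt_censor)
  cpt_tol_cens <- cpt_tol_time >= cfg$cpt_censor

  likert <- function(temp) {
    raw <- 10 * (32 - temp) / 32 + stats::rnorm(ns, 0, cfg$likert_noise_sd)
    as.integer(pmin(pmax(round(raw), 0), 10))
  }

  sessions <- tibble::tibble(
    subject_id = grid$subject_id, session = grid$session,
    qst_thr_temp = thr$temp, qst_thr_time = thr$time,
    qst_thr_censored = thr$censored,
    qst_tol_temp = tol$temp, qst_tol_time = tol$time,
    qst_tol_censored = tol$censored,
    cpt_thr_time = cpt_thr_time, cpt_thr_censored = cpt_thr_cens,
    cpt_tol_time = cpt_tol_time, cpt_tol_censored = cpt_tol_cens,
    likert_qst_thr = likert(thr$temp), likert_qst_tol = likert(tol$temp)
  )

  minutes <- 0:(cfg$cpt_censor %/% 60)
  bp <- tidyr::expand_grid(subject_id = subjects$subject_id,
                           session = seq_len(cfg$sessions),
                           minute = minutes)
  bp <- dplyr::left_join(
    bp,
    subjects[, c("subject_id", "carrier", "bp_sys_baseline",
                 "bp_dia_baseline")],
    by = "subject_id"
  )
  during <- bp$minute >= 1
  bp$systolic <- bp$bp_sys_baseline +
    during * (cfg$pressor_sys + cfg$bp_carrier_effect * bp$carrier) +
    stats::rnorm(nrow(bp), 0, cfg$bp_noise_sd)
  bp$diastolic <- bp$bp_dia_baseline + during * cfg$pressor_dia +
    stats::rnorm(nrow(bp), 0, cfg$bp_noise_sd)
  bp <- bp[, c("subject_id", "session", "minute", "systolic", "diastolic")]

  structure(
    list(subjects = subjects[, c("subject_id", "genotype", "carrier",
                                 "bp_sys_baseline", "bp_dia_baseline")],
         sessions = sessions, bp = bp),
    class = "aei_cohort"
  )
}
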