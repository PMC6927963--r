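test_that("allele-count simulation follows the binomial model", {
  # symmetric case: balanced expression gives a 0.5 minor fraction in both
  # materials
  cfg <- aei_sim_config(
    tibble::tibble(sample_id = "S1", snp_id = "rs1", rho = 1),
    depth = 2e5, error_rate = 0, gdna_bias_sd = 0, replicates = 1, seed = 11
  )
  ac <- simulate_allele_counts(cfg)
  frac <- ac$count_minor / (ac$count_minor + ac$count_common)
  sd3 <- 3 * sqrt(0.5 * 0.5 / 2e5)
  expect_true(all(abs(frac - 0.5) < sd3))

  # rho = 0.5 puts the cDNA minor fraction at 1/3
  cfg <- aei_sim_config(
    tibble::tibble(sample_id = "S1", snp_id = "rs1", rho = 0.5),
    depth = 1e6, error_rate = 0, gdna_bias_sd = 0, replicates = 1, seed = 12
  )
  ac <- simulate_allele_counts(cfg)
  cdna <- ac[ac$material == "cDNA", ]
  frac <- cdna$count_minor / (cdna$count_minor + cdna$count_common)
  expect_lt(abs(frac - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 1e6))

  # an extreme true ratio is recovered at realistic depth
  cfg <- aei_sim_config(
    tibble::tibble(sample_id = "397628", snp_id = "rs13004520",
                   rho = 0.0101),
    depth = 150000, error_rate = 0, gdna_bias_sd = 0, replicates = 1,
    seed = 13
  )
  ac <- simulate_allele_counts(cfg)
  cdna <- ac[ac$material == "cDNA", ]
  expect_equal(cdna$count_minor / cdna$count_common, 0.01,
               tolerance = 0.1)
})

test_that("simulation is deterministic given the seed", {
  cfg <- aei_sim_config(
    tibble::tibble(sample_id = c("A", "B"), snp_id = "rs1",
                   rho = c(0.4, 1.2)),
    depth = 5000, error_rate = 0.01, gdna_bias_sd = 0.06, replicates = 2,
    seed = 99
  )
  expect_identical(simulate_allele_counts(cfg), simulate_allele_counts(cfg))
  amp <- test_amplicon()
  expect_identical(
    as.character(simulate_fastq(amp, 0.3, 200, 0.01, seed = 7)),
    as.character(simulate_fastq(amp, 0.3, 200, 0.01, seed = 7))
  )
  ccfg <- cohort_sim_config(seed = 21)
  expect_identical(simulate_cohort(ccfg), simulate_cohort(ccfg))
})

test_that("config invariants are enforced", {
  samples <- tibble::tibble(sample_id = "S1", snp_id = "rs1", rho = 0.5)
  expect_error(aei_sim_config(dplyr::mutate(samples, rho = 0)), "rho")
  expect_error(aei_sim_config(samples, depth = 0), "depth")
  expect_error(aei_sim_config(samples, error_rate = 0.25), "error_rate")
  expect_error(cohort_sim_config(mean_tt = 33), "32")
  expect_error(cohort_sim_config(qst_censor = 150), "fixed")
})

test_that("FASTQ simulation sets the SNP base as configured", {
  amp <- test_amplicon()
  pos <- amp$snp_offset + 1
  all0 <- simulate_fastq(amp, 0, 50, 0, seed = 1)
  expect_true(all(as.character(Biostrings::subseq(all0, pos, pos)) ==
                    amp$common_allele))
  all1 <- simulate_fastq(amp, 1, 50, 0, seed = 1)
  expect_true(all(as.character(Biostrings::subseq(all1, pos, pos)) ==
                    amp$minor_allele))
  mid <- simulate_fastq(amp, 0.3, 10000, 0, seed = 2)
  frac <- mean(as.character(Biostrings::subseq(mid, pos, pos)) ==
                 amp$minor_allele)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("TaqMan simulation matches the cap convention and calibration", {
  het <- simulate_taqman("het", cq_het = 25, noise_sd = 0, seed = 1)
  expect_equal(het$cq_ref, het$cq_snp)
  expect_equal(taqman_metric(het$cq_ref, het$cq_snp), 1)
  hom <- simulate_taqman("hom_common", cq_het = 25, noise_sd = 0, seed = 1)
  expect_equal(hom$cq_snp, 40)
  m <- taqman_metric(hom$cq_ref, hom$cq_snp)
  expect_lt(m, 0.01)
  expect_equal(call_taqman_genotype(m)$call, "hom_common")
  # noisy heterozygotes stay inside the (0.5, 1.5) window almost surely
  noisy <- simulate_taqman("het", cq_het = 25, noise_sd = 0.3, seed = 4,
                           n = 1000)
  metrics <- taqman_metric(noisy$cq_ref, noisy$cq_snp)
  expect_gte(mean(metrics > 0.5 & metrics < 1.5), 0.99)
})

test_that("pyrosequencing traces renormalize and stay callable", {
  het <- simulate_pyro_trace("het", noise_sd = 0, seed = 1)
  expect_equal(c(het$common_pct, het$minor_pct), c(50, 50))
  hom <- simulate_pyro_trace("hom_common", noise_sd = 0, seed = 1)
  expect_equal(c(hom$common_pct, hom$minor_pct), c(100, 0))
  noisy <- simulate_pyro_trace("het", noise_sd = 5, seed = 2, n = 1000)
  expect_equal(noisy$common_pct + noisy$minor_pct, rep(100, 1000))
  expect_gte(mean(noisy$minor_pct >= 25), 0.99)
})

test_that("clone simulation yields the expected concordant fraction", {
  haps <- list(c(rmr = "C", marker = "C"), c(rmr = "T", marker = "G"))
  clean <- simulate_clone_reads(haps, 20, error_rate = 0, seed = 1)
  pairs <- paste(clean$allele_rmr, clean$allele_marker)
  expect_true(all(pairs %in% c("C C", "T G")))
  # with per-site flip probability e, a clone matches a true haplotype
  # iff both sites are correct or both flipped: (1-e)^2 + e^2
  e <- 0.1
  noisy <- simulate_clone_reads(haps, 5000, error_rate = e, seed = 2)
  pairs <- paste(noisy$allele_rmr, noisy$allele_marker)
  conc <- mean(pairs %in% c("C C", "T G"))
  expected <- (1 - e)^2 + e^2
  expect_lt(abs(conc - expected), 3 * sqrt(expected * (1 - expected) / 5000))
})

test_that("cohort protocol geometry and censoring are exact", {
  co <- simulate_cohort(cohort_sim_config(seed = 31))
  s <- co$sessions
  above <- s$qst_thr_temp > 0
  expect_equal(s$qst_thr_time[above], 32 - s$qst_thr_temp[above])
  expect_true(all(s$qst_thr_time[s$qst_thr_temp == 0] >= 32))
  expect_true(all(s$qst_thr_time <= 152) && all(s$qst_tol_time <= 152))
  expect_true(all(s$cpt_thr_time <= 300) && all(s$cpt_tol_time <= 300))
  expect_equal(s$qst_thr_censored, s$qst_thr_time >= 152)
  expect_equal(s$cpt_thr_censored, s$cpt_thr_time >= 300)
  expect_true(all(s$likert_qst_thr %in% 0:10))
  # empty cohort
  empty <- simulate_cohort(cohort_sim_config(n_tt = 0, n_tc = 0, n_cc = 0))
  expect_equal(nrow(empty$subjects), 0)
})

test_that("equal group means give nominal Kruskal-Wallis size", {
  # type-I calibration of the generator: with no genotype effect the
  # omnibus test on recorded temperatures rejects at about alpha
  n_rep <- 300
  rej <- vapply(seq_len(n_rep), function(i) {
    co <- simulate_cohort(cohort_sim_config(
      n_tt = 15, n_tc = 15, n_cc = 15, mean_tt = 5.4, mean_tc = 5.4,
      mean_cc = 5.4, sessions = 2, seed = 1000 + i
    ))
    s <- average_repeats(co)
    kruskal_wallis(s$qst_thr_temp, s$genotype)$p_value < 0.05
  }, logical(1))
  # binomial(300, 0.05) three-sigma band around 0.05
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("a low CC latent threshold lowers recorded CC temperatures", {
  co <- simulate_cohort(cohort_sim_config(
    n_tt = 50, n_tc = 0, n_cc = 50, mean_tt = 5.4, mean_cc = 0.2,
    between_sd = 2, seed = 42
  ))
  s <- average_repeats(co)
  expect_lt(mean(s$qst_thr_temp[s$genotype == "CC"]),
            mean(s$qst_thr_temp[s$genotype == "TT"]))
})
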