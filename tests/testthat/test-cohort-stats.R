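mini_cohort <- function(sessions_tbl, subjects_tbl = NULL) {
  if (is.null(subjects_tbl)) {
    ids <- unique(sessions_tbl$subject_id)
    subjects_tbl <- tibble::tibble(subject_id = ids, genotype = "TT",
                                   carrier = FALSE)
  }
  structure(list(subjects = subjects_tbl, sessions = sessions_tbl,
                 bp = tibble::tibble()),
            class = "aei_cohort")
}

session_row <- function(subject_id, qst_time, qst_cens,
                        temp = max(0, 32 - qst_time)) {
  tibble::tibble(
    subject_id = subject_id, session = NA_integer_,
    qst_thr_temp = temp, qst_thr_time = qst_time,
    qst_thr_censored = qst_cens,
    qst_tol_temp = 0, qst_tol_time = 152, qst_tol_censored = TRUE,
    cpt_thr_time = 100, cpt_thr_censored = FALSE,
    cpt_tol_time = 300, cpt_tol_censored = TRUE,
    likert_qst_thr = 5L, likert_qst_tol = 8L
  )
}

test_that("within-subject averaging follows the any-event rule", {
  sess <- dplyr::bind_rows(
    session_row("A", 30, FALSE), session_row("A", 40, FALSE),
    session_row("B", 152, TRUE), session_row("B", 152, TRUE),
    session_row("C", 30, FALSE), session_row("C", 152, TRUE)
  )
  s <- average_repeats(mini_cohort(sess))
  a <- s[s$subject_id == "A", ]
  expect_equal(a$qst_thr_time, 35)
  expect_true(a$qst_thr_event)
  b <- s[s$subject_id == "B", ]
  expect_equal(b$qst_thr_time, 152)
  expect_false(b$qst_thr_event)
  c_ <- s[s$subject_id == "C", ]
  expect_equal(c_$qst_thr_time, 30)
  expect_true(c_$qst_thr_event)
  # temperatures average arithmetically
  expect_equal(a$qst_thr_temp, mean(c(2, 0)))
  # fully censored tolerance endpoint stays at the limit without error
  expect_true(all(!s$qst_tol_event) && all(s$qst_tol_time == 152))
})

test_that("Kaplan-Meier matches hand calculations and the ECDF identity", {
  km <- km_fit(c(2, 4), c(TRUE, TRUE))
  expect_equal(km$surv[km$time == 2], 0.5)
  expect_equal(km$surv[km$time == 4], 0)

  expect_equal(km_fit(c(5, 7, 9), c(FALSE, FALSE, FALSE))$surv,
               rep(1, 3))

  # with no censoring the product-limit estimate is 1 - ECDF
  set.seed(3)
  t_ <- round(stats::rexp(40, 0.1), 1) + 0.1
  km <- km_fit(t_, rep(TRUE, 40))
  ecdf_ <- stats::ecdf(t_)
  expect_equal(km$surv, 1 - ecdf_(km$time))

  # survival starts <= 1, never increases
  set.seed(4)
  t2 <- stats::rexp(30, 0.05)
  ev <- stats::runif(30) < 0.7
  km2 <- km_fit(t2, ev)
  expect_true(all(diff(km2$surv) <= 1e-12))
  expect_true(all(km2$surv >= 0 & km2$surv <= 1))

  # invariant to input order
  ord <- sample(seq_along(t2))
  km3 <- km_fit(t2[ord], ev[ord])
  expect_equal(km3, km2)
})

test_that("Cox fit is symmetric, invertible and matches a grid oracle", {
  t_ <- rep(c(1, 2, 3, 5, 8), 2)
  ev <- rep(TRUE, 10)
  grp <- rep(c(0, 1), each = 5)
  fit <- cox_fit(t_, ev, grp)
  expect_equal(fit$hr, 1, tolerance = 1e-6)
  expect_gt(fit$p, 0.9)

  set.seed(9)
  t2 <- stats::rexp(60, 0.1 * exp(0.7 * rep(c(0, 1), each = 30)))
  ev2 <- rep(TRUE, 60)
  g2 <- rep(c(0, 1), each = 30)
  f_ab <- cox_fit(t2, ev2, g2)
  f_ba <- cox_fit(t2, ev2, 1 - g2)
  expect_equal(f_ab$beta, -f_ba$beta, tolerance = 1e-6)

  # 3 subjects, distinct times 1 < 2 < 3, all events, covariate (1,0,1):
  # the partial log-likelihood l(b) = sum_i [b x_i - log sum_{j>=i} e^{b x_j}]
  # has a finite maximizer; find it by grid search and compare
  pl <- function(b) {
    x <- c(1, 0, 1)
    risk <- exp(b * x)
    sum(vapply(1:3, function(i) b * x[i] - log(sum(risk[i:3])), numeric(1)))
  }
  grid <- seq(-5, 5, by = 1e-4)
  b_hat <- grid[which.max(vapply(grid, pl, numeric(1)))]
  fit3 <- cox_fit(c(1, 2, 3), rep(TRUE, 3), c(1, 0, 1))
  expect_equal(fit3$beta, b_hat, tolerance = 1e-3)
})

test_that("Cox estimates of a true hazard ratio of 2 are unbiased", {
  n_runs <- 60
  hrs <- vapply(seq_len(n_runs), function(i) {
    set.seed(700 + i)
    n <- 500
    g <- rep(c(0, 1), each = n)
    t_ <- stats::rexp(2 * n, 0.05 * 2^g)
    cox_fit(t_, rep(TRUE, 2 * n), g)$hr
  }, numeric(1))
  # log HR centred on log 2 with the asymptotic spread (~2/sqrt(events))
  expect_lt(abs(mean(log(hrs)) - log(2)), 3 * 0.066 / sqrt(n_runs))
  expect_lt(stats::sd(log(hrs)), 0.09)
  expect_gt(mean(hrs >= 1.8 & hrs <= 2.2), 0.7)
})

test_that("Cox reports non-convergence on complete separation", {
  t_ <- c(1, 2, 3, 10, 11, 12)
  g <- c(1, 1, 1, 0, 0, 0)
  expect_error(cox_fit(t_, rep(TRUE, 6), g), "converge")
})

test_that("Kruskal-Wallis matches hand ranks and exact enumeration", {
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$statistic, 2.4)
  expect_equal(kw$method, "exact")
  expect_equal(kw$p_value, 1 / 3)

  # identical groups are degenerate
  kw0 <- kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)

  # asymptotic route agrees with the standard implementation
  set.seed(10)
  v <- stats::rnorm(60)
  g <- rep(c("a", "b", "c"), 20)
  kw3 <- kruskal_wallis(v, g)
  ref <- stats::kruskal.test(v, factor(g))
  expect_equal(kw3$statistic, unname(ref$statistic))
  expect_equal(kw3$p_value, ref$p.value)

  # rank statistic is invariant under monotone transformation
  kw_exp <- kruskal_wallis(exp(v), g)
  expect_equal(kw_exp$statistic, kw3$statistic)

  # ties are corrected: H computed from the tie-correction formula
  vt <- c(1, 1, 2, 3, 3, 3)
  gt <- c("a", "a", "a", "b", "b", "b")
  r <- rank(vt)
  n <- 6
  h_raw <- 12 / (n * (n + 1)) *
    sum(tapply(r, gt, sum)^2 / tapply(r, gt, length)) - 3 * (n + 1)
  ties <- table(vt)
  h_exp <- h_raw / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kruskal_wallis(vt, gt, exact = FALSE)$statistic, h_exp)
})

test_that("Dunn-Sidak adjustment is exact and monotone", {
  expect_equal(dunn_sidak(0.05, 3), 1 - 0.95^3)
  expect_equal(dunn_sidak(0.05, 3), 0.142625)
  expect_equal(dunn_sidak(0.2, 1), 0.2)
  expect_equal(dunn_sidak(0, 10), 0)
  expect_equal(dunn_sidak(1, 5), 1)
  p <- seq(0, 1, by = 0.05)
  for (m in 1:6) {
    adj <- dunn_sidak(p, m)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj) >= 0))
    if (m > 1) expect_true(all(adj >= dunn_sidak(p, m - 1)))
  }
})

test_that("Dunn pairwise z tests detect a shifted group", {
  set.seed(12)
  v <- c(stats::rnorm(15, 0), stats::rnorm(15, 0), stats::rnorm(15, 3))
  g <- rep(c("TT", "TC", "CC"), each = 15)
  d <- dunn_test(v, g)
  expect_equal(nrow(d), 3)
  expect_true(all(d$p_adj >= d$p_raw))
  cc_tt <- d[d$comparison %in% c("CC vs TT", "TT vs CC"), ]
  expect_lt(cc_tt$p_adj, 0.05)
  null_pair <- d[d$comparison %in% c("TC vs TT", "TT vs TC"), ]
  expect_gt(null_pair$p_raw, 0.05)
})

test_that("rm_ancova matches baseline-adjusted means on balanced data", {
  set.seed(15)
  n <- 20
  subj <- sprintf("P%02d", 1:(2 * n))
  grp <- rep(c("carrier", "non_carrier"), each = n)
  base <- stats::rnorm(2 * n, 110, 8)
  d <- tidyr::expand_grid(subject = subj, time = 1:3)
  d$group <- grp[match(d$subject, subj)]
  d$baseline <- base[match(d$subject, subj)]
  effect <- ifelse(d$group == "carrier", 6, 0)
  d$change <- 10 + effect + stats::rnorm(nrow(d), 0, 3)

  fit <- rm_ancova(d)
  expect_s4_class(fit$model, "lmerModLmerTest")
  # balanced complete data: LS means differ by about the injected effect
  lsm <- fit$lsmeans
  diffs <- tapply(lsm$emmean, lsm$time,
                  function(x) x[1] - x[2])  # carrier - non_carrier
  expect_equal(unname(mean(diffs)), 6, tolerance = 1.5)
  expect_lt(fit$group_p, 0.01)
  expect_match(fit$covariance, "compound symmetry")

  # rank deficiency is reported, not silently fitted
  tiny <- d[d$subject %in% subj[1:3], ]
  expect_error(rm_ancova(tiny), "rank")
})

test_that("t-test power follows the noncentral t exactly", {
  # independent closed form: both rejection tails of the noncentral t
  power_nct <- function(delta, sd, n, alpha = 0.05) {
    ncp <- abs(delta) / sd * sqrt(n / 2)
    df <- 2 * n - 2
    crit <- stats::qt(1 - alpha / 2, df)
    (1 - stats::pt(crit, df, ncp)) + stats::pt(-crit, df, ncp)
  }
  expect_equal(ttest_power(8.45, 9.5, 20), power_nct(8.45, 9.5, 20),
               tolerance = 1e-6)
  expect_lt(abs(ttest_power(8.45, 9.5, 20) - 0.80), 0.02)
  expect_equal(ttest_power(0, 9.5, 20), 0.05, tolerance = 1e-6)
  expect_gt(ttest_power(100, 9.5, 20), 0.9999)
  # monotone in effect size and n, decreasing in sd
  expect_true(all(diff(vapply(c(2, 5, 8, 12), ttest_power, numeric(1),
                              sd = 9.5, n_per_group = 20)) > 0))
  expect_true(all(diff(vapply(c(10, 20, 40), function(n) {
    ttest_power(8.45, 9.5, n)
  }, numeric(1))) > 0))
  expect_true(all(diff(vapply(c(5, 9.5, 15), function(s) {
    ttest_power(8.45, s, 20)
  }, numeric(1))) < 0))
})
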