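#' Average within-subject repeated sessions per endpoint
#'
#' Each subject performs several QST/CPT sessions; repeated measures are
#' averaged before any group analysis. For a censored time-to-event
#' endpoint the any-event rule applies: if at least one session observed
#' the event, the summary time is the mean of the observed event times
#' and the subject counts as an event; only when every session was
#' censored is the summary the censor limit with the censored flag kept.
#' (This biases summary times downward when sessions mix events and
#' censorings; see the package vignette.) Temperatures and Likert scores
#' are averaged arithmetically.
#'
#' @param cohort An `aei_cohort` (see [simulate_cohort()]), or a list with
#'   tibbles `subjects` and `sessions` in the same schema.
#' @return Tibble with one row per subject: genotype, carrier flag,
#'   summary time and event flag per endpoint (`qst_thr`, `qst_tol`,
#'   `cpt_thr`, `cpt_tol`), mean temperatures and mean Likert scores.
#' @export
average_repeats <- function(cohort) {
  sessions <- cohort$sessions
  subjects <- cohort$subjects

  summarise_tte <- function(time, censored, censor_limit) {
    event <- !censored
    if (any(event)) {
      list(time = mean(time[event]), event = TRUE)
    } else {
      list(time = censor_limit, event = FALSE)
    }
  }

  rows <- lapply(split(sessions, sessions$subject_id), function(s) {
    qst_thr <- summarise_tte(s$qst_thr_time, s$qst_thr_censored, 152)
    qst_tol <- summarise_tte(s$qst_tol_time, s$qst_tol_censored, 152)
    cpt_thr <- summarise_tte(s$cpt_thr_time, s$cpt_thr_censored, 300)
    cpt_tol <- summarise_tte(s$cpt_tol_time, s$cpt_tol_censored, 300)
    tibble::tibble(
      subject_id = s$subject_id[1],
      qst_thr_time = qst_thr$time, qst_thr_event = qst_thr$event,
      qst_tol_time = qst_tol$time, qst_tol_event = qst_tol$event,
      cpt_thr_time = cpt_thr$time, cpt_thr_event = cpt_thr$event,
      cpt_tol_time = cpt_tol$time, cpt_tol_event = cpt_tol$event,
      qst_thr_temp = mean(s$qst_thr_temp),
      qst_tol_temp = mean(s$qst_tol_temp),
      likert_qst_thr = mean(s$likert_qst_thr),
      likert_qst_tol = mean(s$likert_qst_tol)
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(subjects[, intersect(names(subjects),
                                        c("subject_id", "genotype",
                                          "carrier"))],
                   out, by = "subject_id")
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Fits the product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i/n_i)`
#' over the distinct event times, honouring right-censoring.
#'
#' @param times Positive event/censoring times.
#' @param event_flags Logical; `TRUE` for an observed event, `FALSE` for
#'   right-censored.
#' @return Tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, one row per distinct time.
#' @export
km_fit <- function(times, event_flags) {
  if (length(times) == 0) stop("no observations")
  if (any(times <= 0)) stop("times must be > 0")
  fit <- survival::survfit(survival::Surv(times, event_flags) ~ 1)
  s <- summary(fit, censored = TRUE)
  tibble::tibble(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                 n_censor = s$n.censor, surv = s$surv)
}

#' Cox proportional-hazards fit for a group contrast
#'
#' Fits a Cox regression of the (possibly censored) times on the group
#' indicator by partial likelihood, with Breslow handling of ties by
#' default (the 60-second measurement grid makes ties common); Efron is
#' available behind `ties`. Monotone likelihood (complete separation of
#' event orders) is reported as a non-convergence error.
#'
#' @param times Positive times.
#' @param event_flags Logical event indicators.
#' @param group Binary or factor group coding.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List: `hr` (hazard ratio `exp(beta)`), `beta`, `se`, `p`
#'   (two-sided Wald), `n`, `n_event`.
#' @export
cox_fit <- function(times, event_flags, group, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (sum(event_flags) < 1) stop("at least one event is required")
  df <- data.frame(time = times, event = event_flags, group = group)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group, data = df,
                    ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        stop("Cox partial likelihood did not converge (monotone ",
             "likelihood / complete separation): ", conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  list(hr = exp(beta), beta = beta, se = se,
       p = 2 * stats::pnorm(-abs(beta / se)),
       n = fit$n, n_event = fit$nevent)
}

#' Kruskal-Wallis rank test with optional exact permutation p-value
#'
#' Computes the tie-corrected Kruskal-Wallis statistic
#' `H = [12/(N(N+1))] * sum R_i^2/n_i - 3(N+1)` divided by
#' `1 - sum(t^3 - t)/(N^3 - N)`, with the asymptotic chi-square p-value on
#' `k - 1` degrees of freedom. For small pooled samples (`N <= 10`, or on
#' request) the p-value is instead computed by exhaustive enumeration of
#' all assignments of the pooled values to the group sizes.
#'
#' @param values Numeric vector of pooled observations.
#' @param groups Group labels, same length as `values`; >= 2 non-empty
#'   groups.
#' @param exact `NULL` (auto: exact iff `N <= 10`), `TRUE` or `FALSE`.
#' @return List of class `aeikit_test`: `statistic` (H), `df`, `p_value`,
#'   `method` ("asymptotic" or "exact"), `n`.
#' @export
kruskal_wallis <- function(values, groups, exact = NULL) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) == 0)) stop("every group must be non-empty")
  n <- length(values)
  kt <- stats::kruskal.test(values, groups)
  h <- unname(kt$statistic)
  df <- unname(kt$parameter)
  use_exact <- if (is.null(exact)) n <= 10 else isTRUE(exact)
  if (all(values == values[1])) {
    return(structure(list(statistic = 0, df = df, p_value = 1,
                          method = "degenerate", n = n),
                     class = "aeikit_test"))
  }
  if (use_exact) {
    sizes <- as.integer(table(groups))
    perms <- .group_assignments(n, sizes)
    h_perm <- vapply(perms, function(g) {
      unname(stats::kruskal.test(values, factor(g))$statistic)
    }, numeric(1))
    p <- mean(h_perm >= h - 1e-10)
    method <- "exact"
  } else {
    p <- kt$p.value
    method <- "asymptotic"
  }
  structure(list(statistic = h, df = df, p_value = p, method = method,
                 n = n),
            class = "aeikit_test")
}

# All distinct assignments of n items into ordered groups of the given
# sizes, as integer label vectors. Exhaustive; intended for n <= 10.
.group_assignments <- function(n, sizes) {
  assign_rec <- function(remaining, sizes_left, labels) {
    if (length(sizes_left) == 1) {
      labels[remaining] <- length(sizes)
      return(list(labels))
    }
    g <- length(sizes) - length(sizes_left) + 1L
    out <- list()
    for (sel in utils::combn(length(remaining), sizes_left[1],
                             simplify = FALSE)) {
      lab <- labels
      lab[remaining[sel]] <- g
      out <- c(out, assign_rec(remaining[-sel], sizes_left[-1], lab))
    }
    out
  }
  assign_rec(seq_len(n), sizes, integer(n))
}

#' Dunn-Sidak multiplicity adjustment
#'
#' Adjusts p-values for `m` comparisons as `1 - (1 - p)^m`, clamped to
#' `[0, 1]`. Monotone in both `p` and `m` and never below the raw value.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param m Number of comparisons (>= 1).
#' @return Adjusted p-values.
#' @export
dunn_sidak <- function(p, m) {
  if (m < 1) stop("`m` must be >= 1")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  # pmax guards the floating-point identity at m = 1 (adjusted >= raw)
  pmin(1, pmax(p, 1 - (1 - p)^m))
}

#' Dunn's pairwise rank-sum comparisons after Kruskal-Wallis
#'
#' For each group pair, the z statistic is the difference in mean ranks of
#' the pooled sample divided by its null standard error with tie
#' correction: `var = [N(N+1)/12 - sum(t^3 - t)/(12(N-1))](1/n_i + 1/n_j)`.
#' Raw two-sided normal p-values are then Dunn-Sidak adjusted across all
#' pairs.
#'
#' @param values Numeric vector of pooled observations.
#' @param groups Group labels.
#' @return Tibble with `comparison`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_test <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  base_var <- n * (n + 1) / 12 - tie_term
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    i <- groups == pr[1]; j <- groups == pr[2]
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt(base_var * (1 / sum(i) + 1 / sum(j)))
    p_raw <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(comparison = paste(pr[1], "vs", pr[2]), z = z,
                   p_raw = p_raw)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- dunn_sidak(out$p_raw, m)
  out
}

#' Baseline-adjusted repeated-measures ANCOVA for blood pressure
#'
#' Fits change-from-baseline blood pressure with fixed effects for group,
#' time, their interaction and the baseline covariate, and a random
#' subject intercept (compound-symmetry covariance), by REML. Missing
#' cells are tolerated (the mixed model uses all available observations).
#' Returns baseline-adjusted least-squares means with 95% confidence
#' intervals and the Satterthwaite F-tests for the fixed effects.
#'
#' @param data Long-format data frame with columns `subject`, `group`,
#'   `time`, `baseline` and `change` (change from baseline).
#' @return List of class `rm_ancova_fit`: `model` (the lmer fit),
#'   `anova` (fixed-effect F table as a tibble), `lsmeans` (group-by-time
#'   least-squares means with CIs), `interaction_p`, `group_p`, and
#'   `covariance` ("compound symmetry (random subject intercept)").
#' @export
rm_ancova <- function(data) {
  req <- c("subject", "group", "time", "baseline", "change")
  missing <- setdiff(req, names(data))
  if (length(missing) > 0) {
    stop("data missing column(s): ", paste(missing, collapse = ", "))
  }
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$time <- factor(data$time)
  n_fixed <- 1 + 1 + (nlevels(data$group) - 1) + (nlevels(data$time) - 1) +
    (nlevels(data$group) - 1) * (nlevels(data$time) - 1)
  if (nlevels(data$subject) < n_fixed) {
    stop("rank deficiency: ", nlevels(data$subject), " subjects for ",
         n_fixed, " fixed-effect parameters")
  }
  fit <- lmerTest::lmer(change ~ baseline + group * time + (1 | subject),
                        data = data)
  an <- as.data.frame(stats::anova(fit))
  an <- tibble::as_tibble(an, rownames = "term")
  emm <- emmeans::emmeans(fit, ~ group | time)
  lsm <- tibble::as_tibble(as.data.frame(emm))
  p_of <- function(term) {
    i <- which(an$term == term)
    if (length(i) == 1) an$`Pr(>F)`[i] else NA_real_
  }
  structure(
    list(model = fit, anova = an, lsmeans = lsm,
         interaction_p = p_of("group:time"), group_p = p_of("group"),
         covariance = "compound symmetry (random subject intercept)"),
    class = "rm_ancova_fit"
  )
}

#' Power of the two-sided two-sample t test
#'
#' Exact power via the noncentral t distribution with noncentrality
#' `delta * sqrt(n/2) / sd` and `2n - 2` degrees of freedom (both
#' rejection tails counted).
#'
#' @param delta True mean difference (mm Hg or any unit matching `sd`).
#' @param sd Common standard deviation, > 0.
#' @param n_per_group Subjects per group, >= 2.
#' @param alpha Two-sided significance level.
#' @return Power as a proportion in `[0, 1]`.
#' @export
ttest_power <- function(delta, sd, n_per_group, alpha = 0.05) {
  if (sd <= 0) stop("`sd` must be > 0")
  if (n_per_group < 2) stop("`n_per_group` must be >= 2")
  stats::power.t.test(n = n_per_group, delta = abs(delta), sd = sd,
                      sig.level = alpha, type = "two.sample",
                      alternative = "two.sided", strict = TRUE)$power
}
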