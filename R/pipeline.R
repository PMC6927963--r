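#' Run the allelic-imbalance pipeline end to end
#'
#' Orchestrates counting QC, the imbalance report, two-site phasing and
#' risk-allele linkage: counts (given or simulated) are floored, the
#' per-sample imbalance table is built, each sample's clone observations
#' are phased, and the risk allele is linked to the lower-expressed
#' haplotype. Samples failing the read floor or phasing are listed with
#' reasons, never silently dropped.
#'
#' @param counts Allele-count tibble (see [read_counts_table()]), or
#'   `NULL` to simulate from `sim_config`.
#' @param sim_config An [aei_sim_config()] used when `counts` is `NULL`.
#' @param clones Named list (by `sample_id`) of clone-observation tibbles
#'   for [phase_haplotypes()]; samples without clones get verdict `NA`.
#' @param markers Tibble with one row per sample: `sample_id`,
#'   `risk_allele`, `marker_common`, `marker_minor`.
#' @param floor Read floor (default 10,000).
#' @param control_window gDNA control window.
#' @param alpha Significance level for the imbalance test.
#' @param min_concordance,min_clones Phasing acceptance thresholds.
#' @return List of class `aei_run`: `report` (the [aei_report()] tibble),
#'   `verdicts` (sample, concordance, verdict or failure reason),
#'   `skipped` (replicates excluded by the floor) and `manifest`
#'   (thresholds and, when simulating, the seed) — enough to regenerate
#'   every output.
#' @export
run_aei_pipeline <- function(counts = NULL, sim_config = NULL, clones = NULL,
                             markers = NULL, floor = 10000,
                             control_window = c(0.8, 1.25), alpha = 0.05,
                             min_concordance = 0.8, min_clones = 5) {
  if (is.null(counts)) {
    if (is.null(sim_config)) stop("provide `counts` or `sim_config`")
    counts <- simulate_allele_counts(sim_config)
  }
  report <- aei_report(counts, floor = floor,
                       control_window = control_window)
  skipped <- attr(report, "skipped")

  verdicts <- tibble::tibble(sample_id = character(0),
                             concordance = numeric(0),
                             verdict = character(0), note = character(0))
  if (!is.null(clones)) {
    if (is.null(markers)) stop("`markers` is required when phasing")
    rows <- lapply(names(clones), function(sid) {
      res <- report[report$sample_id == sid, ]
      if (nrow(res) == 0) {
        return(tibble::tibble(sample_id = sid, concordance = NA_real_,
                              verdict = NA_character_,
                              note = "no imbalance result"))
      }
      mk <- markers[markers$sample_id == sid, ]
      pair <- tryCatch(
        phase_haplotypes(clones[[sid]], min_concordance = min_concordance,
                         min_clones = min_clones),
        error = function(e) e
      )
      if (inherits(pair, "error")) {
        return(tibble::tibble(sample_id = sid, concordance = NA_real_,
                              verdict = NA_character_,
                              note = conditionMessage(pair)))
      }
      verdict <- link_risk_allele(pair, res[1, ],
                                  risk_allele = mk$risk_allele,
                                  marker_common = mk$marker_common,
                                  marker_minor = mk$marker_minor,
                                  alpha = alpha)
      tibble::tibble(sample_id = sid, concordance = pair$concordance,
                     verdict = verdict, note = NA_character_)
    })
    verdicts <- dplyr::bind_rows(rows)
  }
  manifest <- list(floor = floor, control_window = control_window,
                   alpha = alpha, min_concordance = min_concordance,
                   min_clones = min_clones,
                   seed = if (!is.null(sim_config)) sim_config$seed else NA,
                   simulated = is.null(sim_config) == FALSE,
                   n_skipped = nrow(skipped))
  structure(list(report = report, verdicts = verdicts, skipped = skipped,
                 manifest = manifest),
            class = "aei_run")
}

#' Run the cohort statistics pipeline
#'
#' Averages within-subject repeats, then for each censored endpoint fits
#' Kaplan-Meier curves per group and a Cox group contrast, runs the
#' Kruskal-Wallis omnibus test on QST threshold temperatures with
#' Dunn-Sidak-adjusted pairwise comparisons only when the omnibus test is
#' significant at `alpha` (conditional gating), and fits the
#' baseline-adjusted repeated-measures model to the blood-pressure
#' series. Analyses are produced at two tiers: carrier vs non-carrier and
#' genotype (TT/TC/CC). Groups with a single level are skipped with a
#' recorded reason rather than an error.
#'
#' @param cohort An `aei_cohort` (see [simulate_cohort()]).
#' @param alpha Significance level for the conditional gating.
#' @return List of class `cohort_run`: `summaries` (per-subject averaged
#'   endpoints), `survival` (per tier and endpoint: KM tibbles per group
#'   and the Cox fit or skip reason), `temperature` (per tier:
#'   Kruskal-Wallis result and, when gated in, the Dunn table), `likert`
#'   (same machinery on Likert scores), `bp` (systolic and diastolic
#'   [rm_ancova()] fits or skip reasons), and `notes`.
#' @export
run_cohort_pipeline <- function(cohort, alpha = 0.05) {
  summaries <- average_repeats(cohort)
  notes <- character(0)

  tiers <- list(carrier = factor(ifelse(summaries$carrier, "carrier",
                                        "non_carrier")),
                genotype = factor(summaries$genotype,
                                  levels = intersect(c("TT", "TC", "CC"),
                                                     summaries$genotype)))

  endpoints <- list(qst_thr = c("qst_thr_time", "qst_thr_event"),
                    qst_tol = c("qst_tol_time", "qst_tol_event"),
                    cpt_thr = c("cpt_thr_time", "cpt_thr_event"),
                    cpt_tol = c("cpt_tol_time", "cpt_tol_event"))

  survival_out <- list()
  for (tier in names(tiers)) {
    grp <- tiers[[tier]]
    for (ep in names(endpoints)) {
      cols <- endpoints[[ep]]
      if (!all(cols %in% names(summaries))) {
        notes <- c(notes, paste0("endpoint ", ep, " absent; skipped"))
        next
      }
      times <- summaries[[cols[1]]]
      events <- summaries[[cols[2]]]
      km <- lapply(split(seq_along(times), grp), function(i) {
        km_fit(times[i], events[i])
      })
      cox <- if (nlevels(droplevels(grp)) < 2) {
        paste0("skipped: single group at tier ", tier)
      } else if (sum(events) == 0) {
        "skipped: no events (all observations censored)"
      } else {
        tryCatch(cox_fit(times, events, droplevels(grp)),
                 error = function(e) paste0("skipped: ",
                                            conditionMessage(e)))
      }
      survival_out[[paste(tier, ep, sep = ".")]] <-
        list(tier = tier, endpoint = ep, km = km, cox = cox)
    }
  }

  rank_block <- function(values, grp) {
    if (nlevels(droplevels(grp)) < 2) {
      return(list(omnibus = "skipped: single group", dunn = NULL))
    }
    om <- kruskal_wallis(values, droplevels(grp))
    dunn <- if (om$p_value < alpha && nlevels(droplevels(grp)) > 2) {
      dunn_test(values, droplevels(grp))
    } else NULL
    list(omnibus = om, dunn = dunn)
  }
  temperature <- lapply(tiers, function(grp) {
    rank_block(summaries$qst_thr_temp, grp)
  })
  likert <- lapply(tiers, function(grp) {
    rank_block(summaries$likert_qst_thr, grp)
  })

  bp <- list()
  if (!is.null(cohort$bp) && nrow(cohort$bp) > 0) {
    base <- cohort$bp[cohort$bp$minute == 0, ]
    during <- cohort$bp[cohort$bp$minute > 0, ]
    base_mean <- stats::aggregate(cbind(systolic, diastolic) ~ subject_id,
                                  data = base, FUN = mean)
    names(base_mean) <- c("subject_id", "sys_base", "dia_base")
    long <- merge(during, base_mean, by = "subject_id")
    long <- merge(long, as.data.frame(
      summaries[, c("subject_id", "carrier")]), by = "subject_id")
    for (var in c("systolic", "diastolic")) {
      d <- data.frame(subject = long$subject_id,
                      group = ifelse(long$carrier, "carrier", "non_carrier"),
                      time = long$minute,
                      baseline = long[[paste0(substr(var, 1, 3), "_base")]],
                      change = long[[var]] -
                        long[[paste0(substr(var, 1, 3), "_base")]])
      bp[[var]] <- if (length(unique(d$group)) < 2) {
        "skipped: single group"
      } else {
        tryCatch(rm_ancova(d),
                 error = function(e) paste0("skipped: ",
                                            conditionMessage(e)))
      }
    }
  } else {
    notes <- c(notes, "blood-pressure series absent; skipped")
  }

  structure(list(summaries = summaries, survival = survival_out,
                 temperature = temperature, likert = likert, bp = bp,
                 alpha = alpha, notes = notes),
            class = "cohort_run")
}
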