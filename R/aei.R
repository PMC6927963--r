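#' Allelic imbalance ratio for one barcode
#'
#' The imbalance ratio is the number of minor-allele reads divided by the
#' number of common-allele reads; 1 means no imbalance, 0.5 a 50%
#' reduction of the minor allele. The read floor is enforced first:
#' barcodes with fewer than `floor` allelic reads are not ratio-worthy.
#'
#' @param counts One-row allele-count tibble (see [count_alleles()]).
#' @param floor Minimum allelic read total (see [enforce_read_floor()]).
#' @return The ratio `count_minor / count_common`.
#' @export
allelic_ratio <- function(counts, floor = 10000) {
  enforce_read_floor(counts, floor)
  if (any(counts$count_common == 0)) {
    stop("undefined ratio: common-allele count is zero")
  }
  counts$count_minor / counts$count_common
}

#' Absolute fold change in allelic expression
#'
#' Fold change regardless of which allele is increased:
#' `max(ratio, 1/ratio)`, always >= 1. Computed from the unrounded ratio;
#' the reporting layer rounds to one decimal afterwards.
#'
#' @param ratio Allelic ratio, > 0. A zero-count allele makes the ratio 0
#'   or undefined and is an error here; re-run the ratio with a
#'   pseudo-count if a finite value is required.
#' @return Fold change `>= 1`.
#' @export
fold_change <- function(ratio) {
  if (any(ratio <= 0)) stop("fold change undefined for ratio <= 0")
  pmax(ratio, 1 / ratio)
}

#' Genomic-DNA control check
#'
#' gDNA carries the two alleles 1:1, so its imbalance ratio should be near
#' 1; values outside the window indicate aneuploidy or amplification bias
#' and invalidate the cDNA comparison. The default window `[0.8, 1.25]` is
#' symmetric on the log scale.
#'
#' @param gdna_ratio gDNA minor/common ratio, > 0.
#' @param window Closed interval of acceptable ratios.
#' @return Logical: `TRUE` if the ratio lies inside the window.
#' @export
gdna_control_check <- function(gdna_ratio, window = c(0.8, 1.25)) {
  if (any(gdna_ratio <= 0)) stop("ratio must be > 0")
  gdna_ratio >= window[1] & gdna_ratio <= window[2]
}

#' Test allele-fraction equality between gDNA and cDNA
#'
#' Two-sided test of whether the minor-allele fraction differs between the
#' genomic control and the transcript pool, on the 2x2 material-by-allele
#' contingency table. Fisher's exact test is used when the table total is
#' below 1e5; above that the chi-square approximation with Yates
#' correction is numerically equivalent and much cheaper.
#'
#' @param gdna,cdna One-row allele-count tibbles for the same
#'   sample/marker.
#' @param floor Read floor applied to both materials.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
imbalance_test <- function(gdna, cdna, floor = 10000) {
  enforce_read_floor(gdna, floor)
  enforce_read_floor(cdna, floor)
  tab <- rbind(
    gDNA = c(common = sum(gdna$count_common), minor = sum(gdna$count_minor)),
    cDNA = c(common = sum(cdna$count_common), minor = sum(cdna$count_minor))
  )
  if (any(colSums(tab) == 0)) {
    stop("degenerate table: an allele is absent in both materials")
  }
  if (sum(tab) < 1e5) {
    stats::fisher.test(tab)$p.value
  } else {
    stats::chisq.test(tab, correct = TRUE)$p.value
  }
}

#' Per-sample allelic expression imbalance report
#'
#' Builds the per-sample-by-marker imbalance table: average reads and the
#' average of per-replicate minor/common ratios for each material, the
#' absolute fold change of the (unrounded) mean cDNA ratio, the gDNA
#' control flag, and a two-sided p-value for the cDNA-vs-gDNA
#' allele-fraction difference computed on counts pooled across replicates.
#' A sample missing one material is reported with `NA` in that material's
#' columns rather than dropped.
#'
#' @param counts Allele-count tibble covering one or more samples, with
#'   both materials and >= 1 replicate each.
#' @param floor Read floor; replicates below it are excluded (and listed
#'   in the `skipped` attribute with reasons).
#' @param control_window gDNA window for [gdna_control_check()].
#' @return Tibble with one row per sample by marker, ordered by
#'   `sample_id`: `mean_gdna_reads`, `gdna_ratio`, `mean_cdna_reads`,
#'   `cdna_ratio`, `fold_change`, `gdna_control_pass`, `p_value`.
#'   Attribute `skipped` lists replicates excluded by the read floor.
#' @export
aei_report <- function(counts, floor = 10000, control_window = c(0.8, 1.25)) {
  validate_counts(counts)
  total <- counts$count_common + counts$count_minor
  low <- total < floor
  skipped <- counts[low, ]
  skipped$reason <- if (any(low)) {
    sprintf("below read floor (%d < %d)", total[low], as.integer(floor))
  } else character(0)
  counts <- counts[!low, ]

  summarise_material <- function(df) {
    if (nrow(df) == 0) {
      return(list(reads = NA_real_, ratio = NA_real_))
    }
    list(reads = mean(df$count_common + df$count_minor),
         ratio = mean(df$count_minor / df$count_common))
  }

  keys <- dplyr::distinct(counts[, c("sample_id", "snp_id")])
  keys <- dplyr::arrange(keys, .data$sample_id)
  rows <- purrr::pmap(keys, function(sample_id, snp_id) {
    sub <- counts[counts$sample_id == sample_id & counts$snp_id == snp_id, ]
    g <- sub[sub$material == "gDNA", ]
    c_ <- sub[sub$material == "cDNA", ]
    gs <- summarise_material(g)
    cs <- summarise_material(c_)
    fc <- if (is.na(cs$ratio) || cs$ratio <= 0) NA_real_ else
      fold_change(cs$ratio)
    ctrl <- if (is.na(gs$ratio)) NA else gdna_control_check(gs$ratio,
                                                            control_window)
    p <- if (nrow(g) > 0 && nrow(c_) > 0) imbalance_test(g, c_, floor = floor)
         else NA_real_
    tibble::tibble(
      sample_id = sample_id, snp_id = snp_id,
      mean_gdna_reads = gs$reads, gdna_ratio = gs$ratio,
      mean_cdna_reads = cs$reads, cdna_ratio = cs$ratio,
      fold_change = fc, gdna_control_pass = ctrl, p_value = p
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Render an imbalance report with publication rounding
#'
#' Ratios are rounded to two decimals and fold changes to one, the
#' convention used in the per-sample imbalance table; the underlying
#' report keeps full precision.
#'
#' @param report Output of [aei_report()].
#' @return Tibble with rounded display columns.
#' @export
render_aei_table <- function(report) {
  tibble::tibble(
    sample_id = report$sample_id,
    snp_id = report$snp_id,
    mean_gdna_reads = round(report$mean_gdna_reads),
    gdna_ratio = round(report$gdna_ratio, 2),
    mean_cdna_reads = round(report$mean_cdna_reads),
    cdna_ratio = round(report$cdna_ratio, 2),
    fold_change = round(report$fold_change, 1),
    gdna_control_pass = report$gdna_control_pass,
    p_value = report$p_value
  )
}
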