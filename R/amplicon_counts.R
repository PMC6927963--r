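#' Count alleles at the SNP offset of an amplicon
#'
#' Tallies the base observed at the amplicon's SNP position across a set of
#' reads. Reads shorter than `snp_offset + 1` bases, or whose base quality
#' at the offset is below `min_base_quality`, are skipped (and counted in
#' the `skipped` attribute) rather than guessed at. Bases matching neither
#' allele go to `count_other` and are excluded from downstream ratios.
#'
#' Reads are assumed amplicon-derived and already demultiplexed, so the SNP
#' base is read by direct offset lookup; no alignment is performed.
#' Coordinates are 0-based; qualities are Phred+33.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet], or the path to a
#'   FASTQ file (Phred+33).
#' @param amplicon An [amplicon_spec()].
#' @param min_base_quality Minimum Phred quality at the SNP base
#'   (default 20).
#' @param sample_id,material,replicate Identifiers for the output row.
#' @return One-row tibble of allele counts (`sample_id`, `snp_id`,
#'   `material`, `replicate`, `count_common`, `count_minor`,
#'   `count_other`), with attribute `skipped` holding the number of reads
#'   excluded for length or quality.
#' @export
count_alleles <- function(reads, amplicon, min_base_quality = 20,
                          sample_id = "S1", material = "cDNA",
                          replicate = 1L) {
  stopifnot(inherits(amplicon, "amplicon_spec"))
  if (min_base_quality < 0) stop("`min_base_quality` must be >= 0")
  if (is.character(reads)) {
    # Biostrings warns about dropping its own FASTQ metadata columns; the
    # metadata is unused here
    reads <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(reads),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  widths <- Biostrings::width(reads)
  qwidths <- Biostrings::width(Biostrings::quality(reads))
  bad <- which(widths != qwidths)
  if (length(bad) > 0) {
    stop("malformed FASTQ record '", names(reads)[bad[1]],
         "': sequence length ", widths[bad[1]], " != quality length ",
         qwidths[bad[1]])
  }
  pos <- amplicon$snp_offset + 1L
  long_enough <- widths >= pos
  n_short <- sum(!long_enough)
  reads <- reads[long_enough]

  base <- character(0)
  n_lowq <- 0L
  if (length(reads) > 0) {
    quals <- as(Biostrings::quality(reads), "IntegerList")
    q_at <- vapply(quals, function(q) q[pos], integer(1))
    keep <- q_at >= min_base_quality
    n_lowq <- sum(!keep)
    reads <- reads[keep]
    if (length(reads) > 0) {
      base <- as.character(Biostrings::subseq(reads, start = pos, width = 1))
    }
  }
  out <- tibble::tibble(
    sample_id = sample_id, snp_id = amplicon$name, material = material,
    replicate = as.integer(replicate),
    count_common = sum(base == amplicon$common_allele),
    count_minor = sum(base == amplicon$minor_allele),
    count_other = length(base) - sum(base == amplicon$common_allele) -
      sum(base == amplicon$minor_allele)
  )
  attr(out, "skipped") <- n_short + n_lowq
  out
}

#' Enforce the minimum read depth per barcoded sample
#'
#' Quality control on sequencing depth: a barcode is usable only when its
#' allelic total (`count_common + count_minor`) is at least `floor` reads
#' (default 10,000). Rows below the floor raise an error of class
#' `aeikit_insufficient_reads` carrying the observed total.
#'
#' @param counts Tibble of allele counts (see [count_alleles()]).
#' @param floor Minimum allelic read total (inclusive).
#' @return `counts`, unchanged, when every row passes.
#' @export
enforce_read_floor <- function(counts, floor = 10000) {
  total <- counts$count_common + counts$count_minor
  low <- which(total < floor)
  if (length(low) > 0) {
    i <- low[1]
    lab <- paste0(counts$sample_id[i], "/", counts$snp_id[i], "/",
                  counts$material[i], " replicate ", counts$replicate[i])
    cond <- structure(
      class = c("aeikit_insufficient_reads", "error", "condition"),
      list(message = paste0("insufficient reads for ", lab, ": ", total[i],
                            " < floor ", floor),
           call = sys.call(-1), total = total[i], floor = floor)
    )
    stop(cond)
  }
  counts
}

.counts_required_cols <- c("sample_id", "snp_id", "material", "replicate",
                           "count_common", "count_minor", "count_other")

#' Validate an allele-counts table
#' @noRd
validate_counts <- function(counts) {
  missing <- setdiff(.counts_required_cols, names(counts))
  if (length(missing) > 0) {
    stop("counts table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  bad_mat <- which(!counts$material %in% c("gDNA", "cDNA"))
  if (length(bad_mat) > 0) {
    stop("row ", bad_mat[1], ": material must be 'gDNA' or 'cDNA', got '",
         counts$material[bad_mat[1]], "'")
  }
  cnt <- as.matrix(counts[, c("count_common", "count_minor", "count_other")])
  bad_cnt <- which(rowSums(cnt < 0) > 0)
  if (length(bad_cnt) > 0) {
    stop("row ", bad_cnt[1], ": counts must be non-negative")
  }
  invisible(counts)
}

#' Read and write allele-count tables
#'
#' TSV with a header row and columns `sample_id`, `snp_id`, `material`
#' (gDNA/cDNA), `replicate`, `count_common`, `count_minor`, `count_other`.
#' Unknown extra columns are preserved on read. `material` values outside
#' gDNA/cDNA and negative counts are schema errors naming the row.
#'
#' @param path File path.
#' @return `read_counts_table()` returns a tibble of allele counts.
#' @export
read_counts_table <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE,
                            progress = FALSE)
  if (nrow(counts) > 0) validate_counts(counts)
  else {
    missing <- setdiff(.counts_required_cols, names(counts))
    if (length(missing) > 0) {
      stop("counts table is missing required column(s): ",
           paste(missing, collapse = ", "))
    }
  }
  counts
}

#' @rdname read_counts_table
#' @param counts Tibble of allele counts.
#' @export
write_counts_table <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}
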