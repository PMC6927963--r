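# Shared fixtures: a short amplicon and quick count-row constructors.

test_amplicon <- function() {
  amplicon_spec("rs_test", "ACGTACGTACGTACGTACGT", 9, "C", "A")
}

count_row <- function(common, minor, other = 0L, sample_id = "S1",
                      snp_id = "rs_test", material = "cDNA",
                      replicate = 1L) {
  tibble::tibble(sample_id = sample_id, snp_id = snp_id,
                 material = material, replicate = as.integer(replicate),
                 count_common = as.integer(common),
                 count_minor = as.integer(minor),
                 count_other = as.integer(other))
}

# Counts for one sample in both materials, n replicates each.
sample_counts <- function(gdna_common, gdna_minor, cdna_common, cdna_minor,
                          sample_id = "S1", snp_id = "rs_test") {
  dplyr::bind_rows(
    count_row(gdna_common, gdna_minor, sample_id = sample_id,
              snp_id = snp_id, material = "gDNA"),
    count_row(cdna_common, cdna_minor, sample_id = sample_id,
              snp_id = snp_id, material = "cDNA")
  )
}
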