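# Build a deterministic FISH cohort: gained tumors show 3 test / 2
# centromere signals in every nucleus (ratio 1.5), un-gained 2/2 (ratio 1),
# non-informative tumors have too few nuclei to score.
make_fish_cohort <- function(n_informative, n_gained,
                             myc_in_gained = 0, myc_in_rest = 0,
                             n_noninformative = 0, nuclei_per_tumor = 30) {
  n <- n_informative + n_noninformative
  ids <- sprintf("TT%03d", seq_len(n))
  gained <- c(rep(TRUE, n_gained), rep(FALSE, n - n_gained))
  n_nuc <- c(rep(nuclei_per_tumor, n_informative), rep(5, n_noninformative))
  nuclei <- data.frame(
    tumor_id = rep(ids, times = n_nuc),
    nucleus_id = sequence(n_nuc),
    test_count = rep(ifelse(gained, 3L, 2L), times = n_nuc),
    centromere_count = 2L,
    stringsAsFactors = FALSE
  )
  myc <- rep(FALSE, n)
  if (myc_in_gained > 0) myc[seq_len(myc_in_gained)] <- TRUE
  if (myc_in_rest > 0) myc[n_gained + seq_len(myc_in_rest)] <- TRUE
  annotations <- data.frame(tumor_id = ids, myc_amplified = myc,
                            stringsAsFactors = FALSE)
  list(nuclei = nuclei, annotations = annotations)
}
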