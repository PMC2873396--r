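#' Score one tumor's FISH gain from nucleus-level signal counts
#'
#' The per-tumor ratio is the mean test-probe count divided by the mean
#' centromere count (ratio of means, not mean of per-nucleus ratios, so a
#' few zero-centromere nuclei do not blow up). Gain is called when the
#' ratio reaches `fish_gain_ratio` (inclusive at 1.5). A tumor is
#' informative only when the number of scored nuclei lies within
#' `[min_nuclei, max_nuclei]` and the centromere mean is positive;
#' non-informative tumors get no ratio and no gain call rather than an
#' error, mirroring how such cores are dropped from the denominators.
#'
#' @param test_count,centromere_count non-negative integer signal counts,
#'   one element per scored nucleus.
#' @param thresholds an [analysis_thresholds()].
#' @param min_nuclei,max_nuclei informative range of nuclei per tumor
#'   (default 20-60).
#' @param tumor_id optional identifier carried through.
#' @param myc_amplified optional logical MYCN status annotation.
#' @return A list of class `fish_sample`: `tumor_id`, `n_nuclei`, `ratio`,
#'   `gain`, `informative`, `myc_amplified`.
#' @examples
#' nuc <- rep(c(3, 4), each = 15)  # 30 nuclei, test mean 3.5
#' score_fish_sample(nuc, rep(2, 30))
#' @export
score_fish_sample <- function(test_count, centromere_count,
                              thresholds = analysis_thresholds(),
                              min_nuclei = 20L, max_nuclei = 60L,
                              tumor_id = NA_character_,
                              myc_amplified = NA) {
  if (length(test_count) == 0 || length(test_count) != length(centromere_count)) {
    stop("test and centromere counts must be non-empty and parallel",
         call. = FALSE)
  }
  if (any(test_count < 0) || any(centromere_count < 0)) {
    stop("signal counts must be non-negative", call. = FALSE)
  }
  n <- length(test_count)
  cent_mean <- mean(centromere_count)
  informative <- n >= min_nuclei && n <= max_nuclei && cent_mean > 0
  ratio <- if (informative) mean(test_count) / cent_mean else NA_real_
  structure(
    list(
      tumor_id = tumor_id,
      n_nuclei = n,
      ratio = ratio,
      gain = if (informative) ratio >= thresholds$fish_gain_ratio else NA,
      informative = informative,
      myc_amplified = myc_amplified
    ),
    class = "fish_sample"
  )
}

#' Score a whole FISH cohort
#'
#' Applies [score_fish_sample()] per tumor of a long nucleus-count table
#' and joins MYCN status annotations.
#'
#' @param nuclei data frame with `tumor_id`, `test_count`,
#'   `centromere_count` (one row per nucleus).
#' @param annotations optional data frame with `tumor_id`, `myc_amplified`.
#' @param thresholds an [analysis_thresholds()].
#' @param min_nuclei,max_nuclei informative nucleus range.
#' @return A data frame of class `fish_cohort`: one row per tumor with
#'   `tumor_id`, `n_nuclei`, `ratio`, `gain`, `informative`,
#'   `myc_amplified`.
#' @export
score_fish_cohort <- function(nuclei, annotations = NULL,
                              thresholds = analysis_thresholds(),
                              min_nuclei = 20L, max_nuclei = 60L) {
  ids <- unique(nuclei$tumor_id)
  myc <- rep(NA, length(ids))
  if (!is.null(annotations)) {
    myc <- annotations$myc_amplified[match(ids, annotations$tumor_id)]
  }
  if (any(nuclei$test_count < 0) || any(nuclei$centromere_count < 0)) {
    stop("signal counts must be non-negative", call. = FALSE)
  }
  f <- factor(nuclei$tumor_id, levels = ids)
  n_nuc <- as.integer(table(f))
  test_mean <- as.vector(rowsum(nuclei$test_count, f)) / n_nuc
  cent_mean <- as.vector(rowsum(nuclei$centromere_count, f)) / n_nuc
  informative <- n_nuc >= min_nuclei & n_nuc <= max_nuclei & cent_mean > 0
  ratio <- ifelse(informative, test_mean / cent_mean, NA_real_)
  out <- data.frame(
    tumor_id = ids, n_nuclei = n_nuc, ratio = ratio,
    gain = ifelse(informative, ratio >= thresholds$fish_gain_ratio, NA),
    informative = informative, myc_amplified = myc,
    stringsAsFactors = FALSE
  )
  class(out) <- c("fish_cohort", "data.frame")
  out
}

#' Cross-tabulate locus gain against MYCN amplification
#'
#' Counts informative tumors by joint gain/MYCN status and reports the
#' percentages the clinical bookkeeping uses: percent gained, percent
#' MYCN-amplified, percent with either alteration, and percent of gained
#' tumors that are also MYCN-amplified. Percentages are rounded half-up to
#' whole percent (so 14 of 33 prints as 42). Tumors with unknown MYCN
#' status contribute to `n_informative` and `pct_gain` but are excluded
#' (and counted) from the MYCN-dependent cells.
#'
#' @param cohort a `fish_cohort` data frame.
#' @return A list of class `fish_crosstab`: `n_informative`, `counts`
#'   (both / gain_only / myc_only / neither), `n_myc_unknown`, `pct_gain`,
#'   `pct_myc`, `pct_either`, `pct_both_given_gain`.
#' @export
fish_crosstab <- function(cohort) {
  inf <- cohort[cohort$informative, , drop = FALSE]
  if (nrow(inf) == 0) stop("no informative samples in cohort", call. = FALSE)
  n_inf <- nrow(inf)
  known <- inf[!is.na(inf$myc_amplified), , drop = FALSE]
  counts <- c(
    both = sum(known$gain & known$myc_amplified),
    gain_only = sum(known$gain & !known$myc_amplified),
    myc_only = sum(!known$gain & known$myc_amplified),
    neither = sum(!known$gain & !known$myc_amplified)
  )
  n_gain <- sum(inf$gain)
  pct <- function(num, den) {
    if (den == 0) 0 else as.numeric(round_half_up(100 * num / den))
  }
  structure(
    list(
      n_informative = n_inf,
      counts = counts,
      n_myc_unknown = n_inf - nrow(known),
      pct_gain = pct(n_gain, n_inf),
      pct_myc = pct(counts["both"] + counts["myc_only"], nrow(known)),
      pct_either = pct(counts["both"] + counts["gain_only"] + counts["myc_only"],
                       nrow(known)),
      pct_both_given_gain = pct(counts["both"],
                                counts["both"] + counts["gain_only"])
    ),
    class = "fish_crosstab"
  )
}

#' @export
print.fish_crosstab <- function(x, ...) {
  cat(sprintf("FISH cohort crosstab (%d informative tumor(s))\n",
              x$n_informative))
  cat(sprintf("  gained: %d%%   MYCN-amplified: %d%%   either: %d%%\n",
              x$pct_gain, x$pct_myc, x$pct_either))
  cat(sprintf("  gained tumors also MYCN-amplified: %d%%\n",
              x$pct_both_given_gain))
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=", collapse = "  "),
      "\n")
  if (x$n_myc_unknown > 0) {
    cat(sprintf("  (%d tumor(s) with unknown MYCN status excluded from MYCN cells)\n",
                x$n_myc_unknown))
  }
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson chi-square on an r x c contingency table: statistic
#' sum (O - E)^2 / E with expectations from the margins, df = (r-1)(c-1),
#' upper-tail p. No continuity correction by default (set `correct = TRUE`
#' for the Yates-corrected 2 x 2 variant).
#'
#' @param table numeric matrix of non-negative counts with at least two
#'   non-empty rows and columns.
#' @param correct apply the Yates continuity correction (2 x 2 only).
#' @return A list: `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_independence(matrix(c(10, 0, 0, 10), 2))
#' @export
chi_square_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(!is.finite(table))) {
    stop("table must contain non-negative finite counts", call. = FALSE)
  }
  if (sum(rowSums(table) > 0) < 2 || sum(colSums(table) > 0) < 2) {
    stop("table needs at least two non-empty rows and columns", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
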