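#' Analysis thresholds for the integrative pipeline
#'
#' Bundles every cutoff the pipeline uses, with defaults matching the
#' published analysis: loci with log2 copy-number ratio above 2 are called
#' amplified and above 3.5 high-level amplified; expression extremes are the
#' top and bottom 7 percent of ratios per sample; copy number is summarised
#' over a 50-kb window; FISH gain is a test/centromere signal ratio of at
#' least 1.5; statistical significance is p < 0.05.
#'
#' The loss cutoff deserves a note: a linear copy-number ratio below 0.5
#' (hemizygous loss against a diploid reference) corresponds to a log2 ratio
#' below -1, which is the default here. Set `loss_log2 = 0.5` only if you
#' want the literal reading of "log2 ratio < 0.5", which would call the
#' neutral baseline lost.
#'
#' @param amp_log2 log2 ratio above which a locus is amplified (default 2).
#' @param high_amp_log2 log2 ratio above which an amplification is
#'   high-level (default 3.5). Must exceed `amp_log2`.
#' @param loss_log2 log2 ratio below which a locus is lost (default -1).
#' @param min_probes minimum probes per reported segment (default 2, so
#'   two-probe microamplifications are kept but single-probe outliers are
#'   not).
#' @param max_gap_probes number of interior non-qualifying probes a run may
#'   bridge (default 0).
#' @param window_bp half-width of the copy-number window around a probe
#'   set's genomic position, in bp (default 50000).
#' @param extreme_percentile percentage of ratios called over- and
#'   underexpressed per sample (default 7).
#' @param fish_gain_ratio test/centromere ratio at or above which a tumor
#'   is scored as gained (default 1.5, inclusive).
#' @param alpha significance level for all tests (default 0.05).
#' @return An object of class `analysis_thresholds` (a named list).
#' @examples
#' th <- analysis_thresholds()
#' th$amp_log2
#' @export
analysis_thresholds <- function(amp_log2 = 2,
                                high_amp_log2 = 3.5,
                                loss_log2 = -1,
                                min_probes = 2L,
                                max_gap_probes = 0L,
                                window_bp = 50000L,
                                extreme_percentile = 7,
                                fish_gain_ratio = 1.5,
                                alpha = 0.05) {
  stopifnot(
    is.numeric(amp_log2), is.numeric(high_amp_log2), is.numeric(loss_log2),
    length(amp_log2) == 1, length(high_amp_log2) == 1, length(loss_log2) == 1
  )
  if (!(high_amp_log2 > amp_log2 && amp_log2 > 0 && 0 > loss_log2)) {
    stop("thresholds must satisfy high_amp_log2 > amp_log2 > 0 > loss_log2",
         call. = FALSE)
  }
  if (!(extreme_percentile > 0 && extreme_percentile < 50)) {
    stop("extreme_percentile must lie strictly between 0 and 50", call. = FALSE)
  }
  if (!(fish_gain_ratio > 1)) stop("fish_gain_ratio must exceed 1", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (min_probes < 1) stop("min_probes must be >= 1", call. = FALSE)
  if (max_gap_probes < 0) stop("max_gap_probes must be >= 0", call. = FALSE)
  if (window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  structure(
    list(
      amp_log2 = amp_log2,
      high_amp_log2 = high_amp_log2,
      loss_log2 = loss_log2,
      min_probes = as.integer(min_probes),
      max_gap_probes = as.integer(max_gap_probes),
      window_bp = as.numeric(window_bp),
      extreme_percentile = extreme_percentile,
      fish_gain_ratio = fish_gain_ratio,
      alpha = alpha
    ),
    class = "analysis_thresholds"
  )
}

#' @export
print.analysis_thresholds <- function(x, ...) {
  cat("Analysis thresholds\n")
  cat(sprintf("  amplification:       log2 ratio > %g (high-level > %g)\n",
              x$amp_log2, x$high_amp_log2))
  cat(sprintf("  loss:                log2 ratio < %g\n", x$loss_log2))
  cat(sprintf("  segment:             >= %d probes, bridging <= %d gap probes\n",
              x$min_probes, x$max_gap_probes))
  cat(sprintf("  copy-number window:  +/- %g bp\n", x$window_bp))
  cat(sprintf("  expression extremes: top/bottom %g%% per sample\n",
              x$extreme_percentile))
  cat(sprintf("  FISH gain:           test/centromere ratio >= %g\n",
              x$fish_gain_ratio))
  cat(sprintf("  significance:        p < %g\n", x$alpha))
  invisible(x)
}

# round half away from zero (R's round() is half-even); used wherever the
# reported numbers are conventionally rounded, e.g. "14 of 33 (42%)"
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# evaluate code under a temporary RNG state so generators are deterministic
# in `seed` without clobbering the caller's stream
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
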