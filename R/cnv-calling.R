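#' Classify a locus by its log2 copy-number ratio
#'
#' Thresholded calling: `HIGH_AMP` above `high_amp_log2`, `AMP` above
#' `amp_log2`, `LOSS` below `loss_log2`, otherwise `NEUTRAL`. Vectorised.
#'
#' @param log2_ratio numeric vector of finite log2 copy-number ratios.
#' @param thresholds an [analysis_thresholds()].
#' @return Character vector in `HIGH_AMP`, `AMP`, `LOSS`, `NEUTRAL`.
#' @examples
#' classify_locus(c(2.5, 4, 0, -1.5), analysis_thresholds())
#' @export
classify_locus <- function(log2_ratio, thresholds = analysis_thresholds()) {
  if (any(!is.finite(log2_ratio))) {
    stop("log2_ratio must be finite", call. = FALSE)
  }
  out <- rep("NEUTRAL", length(log2_ratio))
  out[log2_ratio > thresholds$amp_log2] <- "AMP"
  out[log2_ratio > thresholds$high_amp_log2] <- "HIGH_AMP"
  out[log2_ratio < thresholds$loss_log2] <- "LOSS"
  out
}

#' Call amplicon and loss segments from an aCGH profile
#'
#' Scans each chromosome for maximal runs of probes altered in the same
#' direction (amplified = `AMP` or `HIGH_AMP`; lost = `LOSS`), optionally
#' bridging up to `max_gap_probes` interior non-qualifying probes, and
#' reports runs with at least `min_probes` probes as segments. A run
#' containing any `HIGH_AMP` probe is reported as `HIGH_AMP`. Segment
#' boundaries are the positions of the first and last qualifying probes.
#' The default `min_probes = 2` keeps focal two-probe microamplifications
#' while suppressing single-probe outliers.
#'
#' @param probes data frame with `probe_id`, `chromosome`, `position_bp`,
#'   `log2_ratio`, sorted by chromosome then position.
#' @param thresholds an [analysis_thresholds()].
#' @return A data frame of class `cnv_segments`: `chromosome`, `start_bp`,
#'   `end_bp`, `locus_class`, `n_probes`, `median_log2`, `region`.
#' @export
call_segments <- function(probes, thresholds = analysis_thresholds()) {
  need <- c("chromosome", "position_bp", "log2_ratio")
  if (!all(need %in% names(probes))) {
    stop("probes must have columns chromosome, position_bp, log2_ratio",
         call. = FALSE)
  }
  for (ch in unique(probes$chromosome)) {
    pos <- probes$position_bp[probes$chromosome == ch]
    if (is.unsorted(pos)) {
      stop("probes must be sorted by position within each chromosome",
           call. = FALSE)
    }
  }
  cls <- classify_locus(probes$log2_ratio, thresholds)
  direction <- ifelse(cls %in% c("AMP", "HIGH_AMP"), 1L,
                      ifelse(cls == "LOSS", -1L, 0L))
  segs <- list()
  for (ch in unique(probes$chromosome)) {
    idx <- which(probes$chromosome == ch)
    d <- direction[idx]
    i <- 1L
    while (i <= length(idx)) {
      if (d[i] == 0L) { i <- i + 1L; next }
      dir <- d[i]
      members <- i      # qualifying probe offsets within idx
      j <- i + 1L
      gap <- 0L
      while (j <= length(idx)) {
        if (d[j] == dir) {
          members <- c(members, j)
          gap <- 0L
        } else if (d[j] == 0L && gap < thresholds$max_gap_probes) {
          gap <- gap + 1L
        } else break
        j <- j + 1L
      }
      if (length(members) >= thresholds$min_probes) {
        rows <- idx[members]
        seg_cls <- if (dir == -1L) "LOSS"
          else if (any(cls[rows] == "HIGH_AMP")) "HIGH_AMP" else "AMP"
        segs[[length(segs) + 1L]] <- data.frame(
          chromosome = ch,
          start_bp = probes$position_bp[rows[1]],
          end_bp = probes$position_bp[rows[length(rows)]],
          locus_class = seg_cls,
          n_probes = length(rows),
          median_log2 = stats::median(probes$log2_ratio[rows]),
          stringsAsFactors = FALSE
        )
      }
      i <- if (length(members) > 0) members[length(members)] + 1L else i + 1L
    }
  }
  out <- if (length(segs) == 0) {
    data.frame(chromosome = character(), start_bp = numeric(),
               end_bp = numeric(), locus_class = character(),
               n_probes = integer(), median_log2 = numeric(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, segs)
  out$region <- if (nrow(out)) format_region(out) else character()
  class(out) <- c("cnv_segments", "data.frame")
  out
}

#' Format a segment as a megabase region string
#'
#' Boundaries reported in Mb from the p-telomere (`position_bp / 1e6`),
#' rounded half-up to one decimal, e.g. `"14.7-16.0 Mb"`.
#'
#' @param segment data frame with `start_bp` and `end_bp` (vectorised).
#' @return Character vector of region strings.
#' @examples
#' format_region(data.frame(start_bp = 14700000, end_bp = 16049999))
#' @export
format_region <- function(segment) {
  s <- round_half_up(segment$start_bp / 1e6, 1)
  e <- round_half_up(segment$end_bp / 1e6, 1)
  sprintf("%.1f-%.1f Mb", s, e)
}

#' @export
print.cnv_segments <- function(x, ...) {
  cat(sprintf("CNV segments: %d region(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Write segments in IGV-compatible SEG format
#'
#' Tab-delimited SEG: sample, chromosome, start, end, number of probes,
#' segment mean (median log2 ratio here).
#'
#' @param segments a `cnv_segments` data frame.
#' @param sample_id sample name recorded in the first column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, sample_id, path) {
  out <- data.frame(
    Sample = sample_id,
    Chromosome = segments$chromosome,
    Start = segments$start_bp,
    End = segments$end_bp,
    Num_Probes = segments$n_probes,
    Segment_Mean = segments$median_log2,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
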