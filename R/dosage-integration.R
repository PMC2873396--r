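#' Log2 expression ratio of a sample against a reference
#'
#' @param sample_value,reference_value strictly positive intensities
#'   (vectorised).
#' @return `log2(sample_value / reference_value)`.
#' @examples
#' compute_expression_ratio(8, 2)  # 2
#' @export
compute_expression_ratio <- function(sample_value, reference_value) {
  if (any(!is.finite(sample_value)) || any(!is.finite(reference_value)) ||
      any(sample_value <= 0) || any(reference_value <= 0)) {
    stop("sample and reference values must be finite and strictly positive",
         call. = FALSE)
  }
  log2(sample_value / reference_value)
}

#' Assign a genomic position to each expression probe set
#'
#' Probe sets mapping to a gene in the annotation take the gene-interval
#' midpoint (rounded down); unmapped probe sets fall back to the
#' array-vendor position carried in `fallback_chromosome`/`fallback_bp`;
#' probe sets with neither are excluded and counted.
#'
#' @param records data frame with `probe_set_id` and optionally `gene_id`,
#'   `fallback_chromosome`, `fallback_bp`.
#' @param genes gene annotation with `gene_id`, `chromosome`, `start_bp`,
#'   `end_bp`.
#' @return A list: `assigned` (records plus `assigned_chromosome`,
#'   `assigned_position_bp`) and `n_excluded`.
#' @export
assign_position <- function(records, genes) {
  n <- nrow(records)
  chrom <- rep(NA_character_, n)
  pos <- rep(NA_real_, n)
  if ("gene_id" %in% names(records)) {
    m <- match(records$gene_id, genes$gene_id)
    hit <- !is.na(m)
    chrom[hit] <- genes$chromosome[m[hit]]
    pos[hit] <- floor((genes$start_bp[m[hit]] + genes$end_bp[m[hit]]) / 2)
  }
  if (all(c("fallback_chromosome", "fallback_bp") %in% names(records))) {
    fb <- is.na(pos) & !is.na(records$fallback_bp) &
      !is.na(records$fallback_chromosome)
    chrom[fb] <- records$fallback_chromosome[fb]
    pos[fb] <- records$fallback_bp[fb]
  }
  keep <- !is.na(pos)
  if (any(!keep)) {
    warning(sum(!keep), " probe set(s) had neither a gene match nor a ",
            "fallback position and were excluded", call. = FALSE)
  }
  assigned <- records[keep, , drop = FALSE]
  assigned$assigned_chromosome <- chrom[keep]
  assigned$assigned_position_bp <- pos[keep]
  list(assigned = assigned, n_excluded = sum(!keep))
}

#' Windowed median copy number at a genomic position
#'
#' Median of the log2 ratios of aCGH probes on the same chromosome within
#' `window_bp` (inclusive) of each query position; `NA` where no probe
#' qualifies. Even probe counts take the midpoint of the two central
#' values, as `median()` does.
#'
#' @param chromosome,position_bp query position vectors (recycled to equal
#'   length).
#' @param probes aCGH probe data frame (`chromosome`, `position_bp`,
#'   `log2_ratio`).
#' @param window_bp window half-width in bp (default 50000).
#' @return Numeric vector of windowed medians (`NA` = no covering probe).
#' @export
windowed_copy_number <- function(chromosome, position_bp, probes,
                                 window_bp = 50000) {
  n <- max(length(chromosome), length(position_bp))
  chromosome <- rep_len(chromosome, n)
  position_bp <- rep_len(position_bp, n)
  out <- rep(NA_real_, n)
  for (ch in unique(chromosome)) {
    qi <- which(chromosome == ch)
    p <- probes[probes$chromosome == ch, , drop = FALSE]
    if (nrow(p) == 0) next
    ord <- order(p$position_bp)
    pp <- p$position_bp[ord]
    lr <- p$log2_ratio[ord]
    lo <- findInterval(position_bp[qi] - window_bp, pp, left.open = TRUE) + 1
    hi <- findInterval(position_bp[qi] + window_bp, pp)
    for (k in seq_along(qi)) {
      if (hi[k] >= lo[k]) out[qi[k]] <- stats::median(lr[lo[k]:hi[k]])
    }
  }
  out
}

#' Call expression extremes at symmetric percentiles
#'
#' The `k = floor(N x pct / 100)` largest log2 expression ratios in a
#' sample are called `OVER` and the `k` smallest `UNDER`; everything else
#' is `NONE`. Ties at either boundary are resolved by a stable ascending
#' sort on ratio with `probe_set_id` as tie-break, so calls are
#' deterministic.
#'
#' @param ratios numeric vector of log2 expression ratios for one sample.
#' @param probe_set_id identifiers parallel to `ratios` (used only for the
#'   tie rule); defaults to the element index.
#' @param extreme_percentile percentage called at each extreme (default 7).
#' @return Character vector of calls in `OVER`, `UNDER`, `NONE`.
#' @examples
#' table(call_expression_extremes(1:100))
#' @export
call_expression_extremes <- function(ratios,
                                     probe_set_id = as.character(seq_along(ratios)),
                                     extreme_percentile = 7) {
  n <- length(ratios)
  if (n == 0) stop("ratios must be non-empty", call. = FALSE)
  if (length(probe_set_id) != n) {
    stop("probe_set_id must parallel ratios", call. = FALSE)
  }
  k <- floor(n * extreme_percentile / 100)
  calls <- rep("NONE", n)
  if (k > 0) {
    ord <- order(ratios, probe_set_id)
    calls[ord[seq_len(k)]] <- "UNDER"
    calls[ord[seq(n - k + 1, n)]] <- "OVER"
  }
  calls
}

#' Integrate expression probe sets with copy number
#'
#' The core join of the pipeline: positions each probe set
#' ([assign_position()]), attaches the windowed median copy number
#' ([windowed_copy_number()]) and the per-sample percentile expression call
#' ([call_expression_extremes()]). Expression calls are computed over all
#' input records before position mapping, so unmapped probe sets still
#' shape the percentile cutoffs.
#'
#' @param expression data frame with `probe_set_id`, `log2_ratio` and
#'   mapping columns (`gene_id` and/or `fallback_chromosome`/`fallback_bp`).
#' @param probes aCGH probe data frame.
#' @param genes gene annotation.
#' @param thresholds an [analysis_thresholds()].
#' @return A data frame of class `integrated_genes`: `probe_set_id`,
#'   `assigned_chromosome`, `assigned_position_bp`, `copy_number_ratio`
#'   (windowed median log2, `NA` if no probe within the window),
#'   `log2_expression_ratio`, `expression_call`; attribute `n_excluded`
#'   counts unmappable probe sets.
#' @export
integrate_dosage <- function(expression, probes, genes,
                             thresholds = analysis_thresholds()) {
  calls <- call_expression_extremes(expression$log2_ratio,
                                    expression$probe_set_id,
                                    thresholds$extreme_percentile)
  expression$expression_call <- calls
  ap <- assign_position(expression, genes)
  a <- ap$assigned
  a$copy_number_ratio <- windowed_copy_number(
    a$assigned_chromosome, a$assigned_position_bp, probes,
    thresholds$window_bp
  )
  out <- data.frame(
    probe_set_id = a$probe_set_id,
    assigned_chromosome = a$assigned_chromosome,
    assigned_position_bp = a$assigned_position_bp,
    copy_number_ratio = a$copy_number_ratio,
    log2_expression_ratio = a$log2_ratio,
    expression_call = a$expression_call,
    stringsAsFactors = FALSE
  )
  attr(out, "n_excluded") <- ap$n_excluded
  class(out) <- c("integrated_genes", "data.frame")
  out
}

#' Frequency of expression extremes by copy-number bin
#'
#' Splits integrated genes into half-open copy-number bins `(lower, upper]`
#' defined by interior `edges` (with open outer bins to -Inf/+Inf) and
#' reports, per bin, the fraction of genes called `OVER` and `UNDER`. Genes
#' without a defined copy number are excluded and counted.
#'
#' @param integrated an `integrated_genes` data frame.
#' @param edges strictly increasing interior bin edges on the log2 scale;
#'   defaults align with the calling thresholds.
#' @return A data frame of class `copy_number_bins`: `lower_log2`,
#'   `upper_log2`, `n_genes`, `freq_over`, `freq_under` (frequencies `NA`
#'   in empty bins); attribute `n_no_copy_number`.
#' @export
bin_frequencies <- function(integrated,
                            edges = c(-1, -0.5, 0.5, 1, 2, 3.5)) {
  if (length(edges) < 1 || is.unsorted(edges, strictly = TRUE)) {
    stop("edges must be strictly increasing", call. = FALSE)
  }
  has_cn <- !is.na(integrated$copy_number_ratio)
  x <- integrated[has_cn, , drop = FALSE]
  full <- c(-Inf, edges, Inf)
  bin <- findInterval(x$copy_number_ratio, full, left.open = TRUE,
                      rightmost.closed = FALSE)
  nb <- length(full) - 1
  out <- data.frame(
    lower_log2 = full[seq_len(nb)],
    upper_log2 = full[-1],
    n_genes = tabulate(bin, nbins = nb),
    stringsAsFactors = FALSE
  )
  over <- tabulate(bin[x$expression_call == "OVER"], nbins = nb)
  under <- tabulate(bin[x$expression_call == "UNDER"], nbins = nb)
  out$freq_over <- ifelse(out$n_genes > 0, over / out$n_genes, NA_real_)
  out$freq_under <- ifelse(out$n_genes > 0, under / out$n_genes, NA_real_)
  attr(out, "n_no_copy_number") <- sum(!has_cn)
  class(out) <- c("copy_number_bins", "data.frame")
  out
}

#' Amplified genes with concurrent overexpression
#'
#' The candidate-driver report: integrated genes whose windowed copy number
#' exceeds the amplification threshold and whose expression call is
#' `OVER`, sorted by copy number descending.
#'
#' @param integrated an `integrated_genes` data frame.
#' @param thresholds an [analysis_thresholds()].
#' @return Subset of `integrated`, ordered by `copy_number_ratio`
#'   decreasing.
#' @export
amplified_overexpressed <- function(integrated,
                                    thresholds = analysis_thresholds()) {
  sel <- !is.na(integrated$copy_number_ratio) &
    integrated$copy_number_ratio > thresholds$amp_log2 &
    integrated$expression_call == "OVER"
  out <- integrated[sel, , drop = FALSE]
  out[order(-out$copy_number_ratio), , drop = FALSE]
}
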