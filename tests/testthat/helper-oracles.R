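# Independent brute-force oracles used to cross-check the implementation.
# Each deliberately uses a different mechanism than the package code.

# maximal-run scanner over the classified probe vector via rle()
# (no gap bridging -- matches the default max_gap_probes = 0)
oracle_segments <- function(probes, th = analysis_thresholds()) {
  out <- list()
  for (ch in unique(probes$chromosome)) {
    p <- probes[probes$chromosome == ch, , drop = FALSE]
    cls <- classify_locus(p$log2_ratio, th)
    dir <- ifelse(cls %in% c("AMP", "HIGH_AMP"), 1L, ifelse(cls == "LOSS", -1L, 0L))
    r <- rle(dir)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0L || r$lengths[k] < th$min_probes) next
      i <- starts[k]:ends[k]
      seg_cls <- if (r$values[k] == -1L) "LOSS"
        else if (any(cls[i] == "HIGH_AMP")) "HIGH_AMP" else "AMP"
      out[[length(out) + 1]] <- data.frame(
        chromosome = ch, start_bp = p$position_bp[i[1]],
        end_bp = p$position_bp[i[length(i)]], locus_class = seg_cls,
        n_probes = length(i), median_log2 = median(p$log2_ratio[i]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# full-scan distance filter + median
oracle_window_median <- function(chrom, pos, probes, w) {
  sel <- probes$chromosome == chrom & abs(probes$position_bp - pos) <= w
  if (!any(sel)) return(NA_real_)
  median(probes$log2_ratio[sel])
}

# full-sort top-k/bottom-k with the stable tie rule
oracle_extreme_calls <- function(ratios, ids, pct) {
  n <- length(ratios)
  k <- floor(n * pct / 100)
  calls <- rep("NONE", n)
  if (k > 0) {
    ord <- order(ratios, ids)
    calls[ord[1:k]] <- "UNDER"
    calls[ord[(n - k + 1):n]] <- "OVER"
  }
  calls
}

# exact one-sided MWW p by enumerating every assignment of pooled values
# to the x-labels (tie-free inputs only)
oracle_mww_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  combos <- combn(length(pooled), n)
  u_all <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(u_all >= u_obs)
}

# hand product-limit rule, events before censorings at ties
oracle_km <- function(time, event) {
  ord <- order(time, !event)
  time <- time[ord]; event <- as.logical(event)[ord]
  s <- 1
  at_risk <- length(time)
  out <- NULL
  for (t in unique(time)) {
    d <- sum(time == t & event)
    n_t <- sum(time >= t)
    if (d > 0) {
      s <- s * (1 - d / n_t)
      out <- rbind(out, data.frame(time = t, survival = s))
    }
  }
  out
}

# textbook Pearson chi-square from margins
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

# exact binomial 99% acceptance band for a count of successes
binom_band <- function(n, p) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p))
}

expect_in_band <- function(count, n, p) {
  band <- binom_band(n, p)
  expect_gte(count, band[1])
  expect_lte(count, band[2])
}
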