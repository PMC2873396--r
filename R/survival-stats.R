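#' Assign a three-level risk group from FISH findings
#'
#' `MYCN_AMP` whenever MYCN is amplified (the worst-prognosis marker
#' dominates, so the rare tumor carrying both alterations lands here;
#' flip `myc_dominates` to place it in the gain group instead), else
#' `GAIN_12Q24` when the locus gain is present, else `NEITHER`. Records
#' with a missing flag come back `NA` so callers can drop and count them.
#'
#' @param gain,myc_amplified logical vectors (recycled to equal length).
#' @param myc_dominates if `FALSE`, tumors with both alterations are
#'   assigned to `GAIN_12Q24`.
#' @return Character vector in `MYCN_AMP`, `GAIN_12Q24`, `NEITHER`, `NA`.
#' @examples
#' assign_risk_group(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
assign_risk_group <- function(gain, myc_amplified, myc_dominates = TRUE) {
  n <- max(length(gain), length(myc_amplified))
  gain <- rep_len(gain, n)
  myc <- rep_len(myc_amplified, n)
  out <- rep(NA_character_, n)
  known <- !is.na(gain) & !is.na(myc)
  if (myc_dominates) {
    out[known] <- ifelse(myc[known], "MYCN_AMP",
                         ifelse(gain[known], "GAIN_12Q24", "NEITHER"))
  } else {
    out[known] <- ifelse(gain[known], "GAIN_12Q24",
                         ifelse(myc[known], "MYCN_AMP", "NEITHER"))
  }
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival curve by the product-limit rule: at each distinct event time t
#' with d events among n at risk, S is multiplied by (1 - d/n);
#' censorings at t leave the curve unchanged and reduce the risk set after
#' events at the same time (events precede censorings at ties). Backed by
#' [survival::survfit()].
#'
#' @param time positive follow-up times.
#' @param event logical (or 0/1) event indicators; `FALSE` = censored.
#' @return A data frame of class `km_curve`, one row per distinct event
#'   time: `time`, `n_risk`, `n_event`, `survival`.
#' @examples
#' km_estimate(1:4, rep(TRUE, 4))$survival  # 0.75 0.50 0.25 0.00
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("at least one record required", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be finite and positive", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(
    time = fit$time[keep],
    n_risk = fit$n.risk[keep],
    n_event = fit$n.event[keep],
    survival = fit$surv[keep]
  )
  class(out) <- c("km_curve", "data.frame")
  out
}

#' k-sample log-rank test
#'
#' At each distinct event time the observed events per group are compared
#' with their hypergeometric expectation given the risk sets; the
#' statistic is the quadratic form over k-1 groups and is referred to a
#' chi-square distribution with k-1 degrees of freedom. Backed by
#' [survival::survdiff()].
#'
#' @param time,event as in [km_estimate()].
#' @param group group labels (2 or more non-empty groups).
#' @return A list of class `logrank_test`: `statistic`, `df`, `p_value`,
#'   `n_groups`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stop("need at least two groups", call. = FALSE)
  if (sum(as.integer(event)) == 0) {
    stop("log-rank test undefined with no events", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  structure(
    list(
      statistic = unname(sd$chisq),
      df = nlevels(group) - 1L,
      p_value = stats::pchisq(sd$chisq, df = nlevels(group) - 1L,
                              lower.tail = FALSE),
      n_groups = nlevels(group),
      observed = as.vector(sd$obs),
      expected = as.vector(sd$exp)
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Three-group survival stratification
#'
#' Convenience wrapper tying the FISH scoring to survival: assigns risk
#' groups from per-tumor gain and MYCN flags, estimates a Kaplan-Meier
#' curve per group and runs the log-rank test across groups.
#'
#' @param records data frame with `time`, `event`, and either `risk_group`
#'   or both `gain` and `myc_amplified`.
#' @return A list of class `risk_stratification`: `curves` (named list of
#'   `km_curve`s), `test` (a `logrank_test`), `n_per_group`,
#'   `n_excluded` (records with unknown flags).
#' @export
stratify_survival <- function(records) {
  if (!"risk_group" %in% names(records)) {
    records$risk_group <- assign_risk_group(records$gain,
                                            records$myc_amplified)
  }
  keep <- !is.na(records$risk_group)
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0) stop("no records with a known risk group", call. = FALSE)
  groups <- split(r, r$risk_group)
  curves <- lapply(groups, function(g) km_estimate(g$time, g$event))
  structure(
    list(
      curves = curves,
      test = logrank_test(r$time, r$event, r$risk_group),
      n_per_group = vapply(groups, nrow, integer(1)),
      n_excluded = sum(!keep)
    ),
    class = "risk_stratification"
  )
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat("Risk stratification\n")
  cat("  group sizes:",
      paste(names(x$n_per_group), x$n_per_group, sep = "=", collapse = "  "),
      "\n")
  print(x$test)
  invisible(x)
}
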