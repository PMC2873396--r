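#' One-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' Tests whether `x` is stochastically greater than `y` (or the two-sided
#' alternative). The exact null distribution is used when the sample-size
#' product `|x| * |y|` is at most 400 and the pooled data are tie-free;
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction is used. Backed by [stats::wilcox.test()].
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return A list: `U` (Mann-Whitney U for `x`), `p_value`, `exact`
#'   (whether the exact branch was taken).
#' @examples
#' mww_rank_sum(c(4, 5, 6), c(1, 2, 3))$p_value  # 1/20
#' @export
mww_rank_sum <- function(x, y, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = use_exact,
                       correct = TRUE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = use_exact)
}

#' Screen genes for tumor-elevated expression against healthy groups
#'
#' For each gene, three one-sided Mann-Whitney-Wilcoxon tests compare the
#' tumor (neuroblastoma) samples against (i) all healthy nervous system
#' samples (peripheral plus central), (ii) healthy peripheral nervous
#' system samples only, and (iii) all healthy samples. A gene passes when
#' all three p-values fall below `alpha` — raw p-values, no
#' multiple-testing correction, matching how such screens report
#' per-comparison significance (a Bonferroni option is available via
#' `adjust`). Genes absent from the compendium, or with no usable value in
#' the tumor class or any comparison group, are marked non-informative.
#'
#' @param compendium a `compendium` list (`expression` genes x samples
#'   matrix, `annotations` with `sample_id`, `tissue_class`) as produced by
#'   [generate_compendium()] or assembled from files.
#' @param gene_list character vector of genes to screen (e.g. all genes in
#'   an amplicon).
#' @param thresholds an [analysis_thresholds()] (supplies `alpha`).
#' @param alternative alternative hypothesis passed to [mww_rank_sum()].
#' @param adjust `"none"` (default) or `"bonferroni"` across the screened
#'   gene list, applied per comparison.
#' @return A data frame of class `screen_result`: `gene`, `informative`,
#'   `p_vs_nervous`, `p_vs_pns`, `p_vs_all_healthy`, `passes`; attributes
#'   `n_informative`, `pct_informative` (half-up to 0.1 percent).
#' @export
screen_genes <- function(compendium, gene_list,
                         thresholds = analysis_thresholds(),
                         alternative = "greater",
                         adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  expr <- compendium$expression
  ann <- compendium$annotations
  cls <- ann$tissue_class[match(colnames(expr), ann$sample_id)]
  nb <- cls == "NEUROBLASTOMA"
  groups <- list(
    nervous = cls %in% c("HEALTHY_PNS", "HEALTHY_CNS"),
    pns = cls == "HEALTHY_PNS",
    all_healthy = cls %in% c("HEALTHY_PNS", "HEALTHY_CNS", "HEALTHY_OTHER")
  )
  if (!any(nb) || any(!vapply(groups, any, logical(1)))) {
    stop("tumor class and every healthy comparison group must be non-empty",
         call. = FALSE)
  }
  res <- data.frame(
    gene = gene_list,
    informative = FALSE,
    p_vs_nervous = NA_real_,
    p_vs_pns = NA_real_,
    p_vs_all_healthy = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(gene_list)) {
    g <- gene_list[i]
    if (!g %in% rownames(expr)) next
    v <- expr[g, ]
    xv <- v[nb]; xv <- xv[!is.na(xv)]
    if (length(xv) == 0) next
    ps <- vapply(groups, function(sel) {
      yv <- v[sel]; yv <- yv[!is.na(yv)]
      if (length(yv) == 0) return(NA_real_)
      mww_rank_sum(xv, yv, alternative)$p_value
    }, numeric(1))
    if (any(is.na(ps))) next
    res$informative[i] <- TRUE
    res$p_vs_nervous[i] <- ps[["nervous"]]
    res$p_vs_pns[i] <- ps[["pns"]]
    res$p_vs_all_healthy[i] <- ps[["all_healthy"]]
  }
  if (adjust == "bonferroni") {
    n_inf <- sum(res$informative)
    for (col in c("p_vs_nervous", "p_vs_pns", "p_vs_all_healthy")) {
      res[[col]] <- pmin(1, res[[col]] * n_inf)
    }
  }
  res$passes <- res$informative &
    res$p_vs_nervous < thresholds$alpha &
    res$p_vs_pns < thresholds$alpha &
    res$p_vs_all_healthy < thresholds$alpha
  res$passes[!res$informative] <- FALSE
  attr(res, "n_informative") <- sum(res$informative)
  attr(res, "pct_informative") <-
    as.numeric(round_half_up(100 * sum(res$informative) / nrow(res), 1))
  class(res) <- c("screen_result", "data.frame")
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Expression screen: %d/%d genes informative (%.1f%%), %d pass\n",
              attr(x, "n_informative"), nrow(x), attr(x, "pct_informative"),
              sum(x$passes)))
  if (nrow(x)) {
    shown <- x
    for (col in c("p_vs_nervous", "p_vs_pns", "p_vs_all_healthy")) {
      shown[[col]] <- ifelse(is.na(x[[col]]), NA,
                             ifelse(x[[col]] < 1e-16, "<1e-16",
                                    signif(x[[col]], 3)))
    }
    print.data.frame(shown, row.names = FALSE, ...)
  }
  invisible(x)
}

#' Check positive-control genes
#'
#' Runs the screen on known tumor-activated control genes (such as MYCN,
#' MEIS1 and ALK) and warns — without failing — when a control is missing
#' from the compendium or does not pass, since failing controls mean the
#' compendium lacks power to see true activation.
#'
#' @param compendium a `compendium` list.
#' @param control_genes character vector of control gene names.
#' @param thresholds an [analysis_thresholds()].
#' @return A list of class `control_report`: `results` (a `screen_result`
#'   over the controls), `all_pass`, `missing` (controls absent from the
#'   compendium).
#' @export
check_positive_controls <- function(compendium, control_genes,
                                    thresholds = analysis_thresholds()) {
  missing <- setdiff(control_genes, rownames(compendium$expression))
  if (length(missing) > 0) {
    warning("positive control(s) absent from compendium: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  results <- screen_genes(compendium, control_genes, thresholds)
  all_pass <- length(missing) == 0 && all(results$passes)
  if (!all_pass) {
    warning("not all positive controls pass the screen", call. = FALSE)
  }
  structure(list(results = results, all_pass = all_pass, missing = missing),
            class = "control_report")
}

#' Rank passing genes by activation strength
#'
#' Orders the genes that pass the screen by an effect-size score: the
#' difference between the tumor-class median and the all-healthy median
#' expression (larger = stronger activation), with ties broken by the
#' smaller p-value against all healthy samples.
#'
#' @param results a `screen_result`.
#' @param compendium the `compendium` the screen was run on.
#' @return A data frame: passing genes with `activation_score`, ordered
#'   strongest first; empty when nothing passes.
#' @export
rank_activation <- function(results, compendium) {
  pass <- results[results$passes, , drop = FALSE]
  if (nrow(pass) == 0) {
    pass$activation_score <- numeric(0)
    return(as.data.frame(pass))
  }
  expr <- compendium$expression
  ann <- compendium$annotations
  cls <- ann$tissue_class[match(colnames(expr), ann$sample_id)]
  nb <- cls == "NEUROBLASTOMA"
  healthy <- cls %in% c("HEALTHY_PNS", "HEALTHY_CNS", "HEALTHY_OTHER")
  pass$activation_score <- vapply(pass$gene, function(g) {
    v <- expr[g, ]
    stats::median(v[nb], na.rm = TRUE) -
      stats::median(v[healthy], na.rm = TRUE)
  }, numeric(1))
  out <- pass[order(-pass$activation_score, pass$p_vs_all_healthy), ,
              drop = FALSE]
  rownames(out) <- NULL
  as.data.frame(out)
}
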