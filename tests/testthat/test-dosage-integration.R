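th <- analysis_thresholds()

test_that("expression ratio is log2(sample/reference) and rejects bad input", {
  expect_equal(compute_expression_ratio(8, 2), 2)
  expect_equal(compute_expression_ratio(5, 5), 0)
  set.seed(1)
  s <- runif(1000, 0.01, 1000); r <- runif(1000, 0.01, 1000)
  expect_equal(compute_expression_ratio(s, r), log(s / r) / log(2),
               tolerance = 1e-12)
  expect_error(compute_expression_ratio(0, 1), "positive")
  expect_error(compute_expression_ratio(1, -2), "positive")
})

test_that("position assignment: gene midpoint, vendor fallback, exclusion", {
  genes <- data.frame(gene_id = "ENSG1", chromosome = "chr1",
                      start_bp = 100, end_bp = 200)
  rec <- data.frame(
    probe_set_id = c("a", "b", "c"),
    gene_id = c("ENSG1", "MISSING", "MISSING"),
    fallback_chromosome = c(NA, "chr1", NA),
    fallback_bp = c(NA, 5000, NA),
    stringsAsFactors = FALSE
  )
  expect_warning(res <- assign_position(rec, genes), "excluded")
  expect_equal(res$n_excluded, 1)
  expect_equal(res$assigned$assigned_position_bp, c(150, 5000))
  expect_equal(res$assigned$assigned_chromosome, c("chr1", "chr1"))
})

test_that("windowed median matches examples and the brute-force oracle", {
  probes <- data.frame(chromosome = "chr1",
                       position_bp = c(100000, 120000, 200000),
                       log2_ratio = c(1, 2, 5))
  expect_equal(windowed_copy_number("chr1", 110000, probes, 50000), 1.5)
  expect_true(is.na(windowed_copy_number("chr9", 110000, probes, 50000)))
  # inclusive at exactly the window edge
  expect_equal(windowed_copy_number("chr1", 150000, probes, 50000),
               median(c(1, 2, 5)))

  set.seed(5)
  big <- data.frame(
    chromosome = sample(c("chr1", "chr2"), 400, replace = TRUE),
    position_bp = sample(1:5e6, 400),
    log2_ratio = rnorm(400)
  )
  qc <- sample(c("chr1", "chr2", "chr3"), 500, replace = TRUE)
  qp <- sample(1:5e6, 500)
  got <- windowed_copy_number(qc, qp, big, 50000)
  want <- mapply(oracle_window_median, qc, qp,
                 MoreArgs = list(probes = big, w = 50000))
  expect_equal(got, unname(want))
  # invariant to probe input order
  shuf <- big[sample(nrow(big)), ]
  expect_equal(windowed_copy_number(qc, qp, shuf, 50000), got)
})

test_that("percentile extremes call exactly floor(N*pct/100) per side", {
  calls <- call_expression_extremes(1:100, sprintf("ps%03d", 1:100), 7)
  expect_equal(which(calls == "OVER"), 94:100)
  expect_equal(which(calls == "UNDER"), 1:7)

  # all ratios equal: stable probe_set_id order decides
  ties <- call_expression_extremes(rep(1, 100), sprintf("ps%03d", 1:100), 7)
  expect_equal(which(ties == "UNDER"), 1:7)
  expect_equal(which(ties == "OVER"), 94:100)

  expect_error(call_expression_extremes(numeric(0)), "non-empty")

  # symmetric count invariant across sizes and percentiles
  set.seed(8)
  for (n in c(15, 100, 777)) {
    for (pct in c(3, 7, 20)) {
      cl <- call_expression_extremes(rnorm(n), extreme_percentile = pct)
      expect_equal(sum(cl == "OVER"), floor(n * pct / 100))
      expect_equal(sum(cl == "UNDER"), floor(n * pct / 100))
    }
  }

  # full-sort oracle at N = 1000 with duplicated values
  set.seed(9)
  r <- sample(round(rnorm(1000), 1))
  ids <- sprintf("ps%04d", sample(1000))
  expect_equal(call_expression_extremes(r, ids, 7),
               oracle_extreme_calls(r, ids, 7))
})

test_that("bin frequencies split on half-open edges and flag empty bins", {
  integ <- data.frame(
    probe_set_id = c("a", "b", "c", "d"),
    copy_number_ratio = c(0, 0, 3, 3),
    expression_call = c("NONE", "NONE", "OVER", "OVER"),
    stringsAsFactors = FALSE
  )
  b <- bin_frequencies(integ, edges = 1)
  expect_equal(b$n_genes, c(2, 2))
  expect_equal(b$freq_over, c(0, 1))

  b2 <- bin_frequencies(integ, edges = c(1, 5))
  expect_equal(b2$n_genes, c(2, 2, 0))
  expect_true(is.na(b2$freq_over[3]))

  expect_error(bin_frequencies(integ, edges = c(2, 1)), "increasing")
  # genes without copy number are excluded but counted
  integ$copy_number_ratio[1] <- NA
  b3 <- bin_frequencies(integ, edges = 1)
  expect_equal(attr(b3, "n_no_copy_number"), 1)
  expect_equal(sum(b3$n_genes), 3)
})

test_that("overexpression frequency rises with copy number under a dosage effect", {
  gen <- generate_genome(4, 2.5e7, 5000, seed = 31)
  seg <- planted_segments(
    rep(c("chr1", "chr2", "chr3"), each = 1),
    c(1, 1, 1), c(8e6, 1.2e7, 1.5e7), c(1, 2.5, 4)
  )
  cfg <- sim_config(seed = 31, dosage_slope = 1, expression_noise_sd = 0.4,
                    noise_sd = 0.15)
  prof <- generate_cgh_profile(gen, seg, cfg)
  expr <- generate_expression(gen, seg, cfg)
  integ <- integrate_dosage(expr, prof, gen$genes, th)
  b <- bin_frequencies(integ)
  occ <- !is.na(b$freq_over) & b$n_genes >= 30
  # monotone non-decreasing across occupied bins, within binomial noise
  f <- b$freq_over[occ]
  se <- sqrt(pmax(f * (1 - f), 0.25 / b$n_genes[occ]) / b$n_genes[occ])
  for (i in seq_len(sum(occ) - 1)) {
    expect_gte(f[i + 1] - f[i], -3 * (se[i] + se[i + 1]))
  }
  # and the top bin dominates the neutral bin outright
  expect_gt(f[length(f)], f[1])
})

test_that("amplified+overexpressed report recovers the planted amplicon genes", {
  gen <- generate_genome(1, 1e7, 300, seed = 41)
  # amplicon covering ~5% of genes so the 7% call rule can cover it
  seg <- planted_segments("chr1", 1, 5e5, 4)
  cfg <- sim_config(seed = 41, dosage_slope = 1, expression_noise_sd = 0.1,
                    noise_sd = 0.05)
  prof <- generate_cgh_profile(gen, seg, cfg)
  expr <- generate_expression(gen, seg, cfg)
  integ <- integrate_dosage(expr, prof, gen$genes, th)
  rep_genes <- amplified_overexpressed(integ, th)
  truth <- integ$probe_set_id[integ$assigned_position_bp <= 5e5]
  expect_setequal(rep_genes$probe_set_id, truth)
  # sorted by copy number descending
  expect_false(is.unsorted(rev(rep_genes$copy_number_ratio)))
  # simple inclusion/exclusion semantics
  fake <- data.frame(probe_set_id = c("x", "y"),
                     copy_number_ratio = c(4.2, 4.2),
                     expression_call = c("OVER", "NONE"))
  expect_equal(amplified_overexpressed(fake, th)$probe_set_id, "x")
  empty <- fake[0, ]
  expect_equal(nrow(amplified_overexpressed(empty, th)), 0)
})

test_that("most genes inside a focal planted amplicon get OVER calls", {
  gen <- generate_genome(1, 2e7, 600, seed = 51)
  seg <- planted_segments("chr1", 1, 1e6, 4)  # ~5% of genes
  cfg <- sim_config(seed = 51, dosage_slope = 1, expression_noise_sd = 0.1,
                    noise_sd = 0.1)
  expr <- generate_expression(gen, seg, cfg)
  calls <- call_expression_extremes(expr$log2_ratio, expr$probe_set_id, 7)
  inside <- expr$position_bp <= 1e6
  expect_gte(mean(calls[inside] == "OVER"), 0.95)
})
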