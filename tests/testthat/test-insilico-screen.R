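th <- analysis_thresholds()

test_that("one-sided rank-sum test matches its exact examples", {
  r <- mww_rank_sum(c(4, 5, 6), c(1, 2, 3), "greater")
  expect_equal(r$p_value, 1 / 20)
  expect_true(r$exact)
  expect_equal(r$U, 9)

  # identical samples carry no evidence of elevation
  r2 <- mww_rank_sum(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_gte(r2$p_value, 0.5)

  expect_error(mww_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact p equals brute-force enumeration for all small sizes", {
  set.seed(26)
  for (rep in 1:40) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    v <- sample(1:1000, n + m)  # tie-free
    x <- v[1:n] + 0.5; y <- v[-(1:n)]
    got <- mww_rank_sum(x, y, "greater")
    expect_true(got$exact)
    expect_equal(got$p_value, oracle_mww_exact(x, y), tolerance = 1e-12)
  }
})

test_that("exact and normal branches agree near the branch boundary", {
  set.seed(27)
  for (rep in 1:10) {
    x <- rnorm(20); y <- rnorm(20)  # product 400: exact branch
    pe <- mww_rank_sum(x, y, "greater")$p_value
    pn <- suppressWarnings(
      wilcox.test(x, y, alternative = "greater", exact = FALSE,
                  correct = TRUE)$p.value
    )
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("shifting the tumor sample up never increases the one-sided p", {
  set.seed(28)
  x <- rnorm(15); y <- rnorm(20)
  p0 <- mww_rank_sum(x, y, "greater")$p_value
  for (shift in c(0.5, 1, 2)) {
    expect_lte(mww_rank_sum(x + shift, y, "greater")$p_value, p0 + 1e-12)
  }
})

test_that("rank-sum type-I error is calibrated at the 5% level", {
  set.seed(30)
  n_genes <- 500
  rejections <- sum(replicate(n_genes, {
    mww_rank_sum(rnorm(25), rnorm(25), "greater")$p_value < 0.05
  }))
  expect_in_band(rejections, n_genes, 0.05)
})

test_that("screen passes planted genes, reports informative fraction", {
  cfg <- sim_config(seed = 35, elevated_effect = 3)
  present <- sprintf("AMPG%02d", 1:25)
  elevated <- present[1:5]
  comp <- generate_compendium(30, present, elevated, cfg)
  gene_list <- sprintf("AMPG%02d", 1:40)  # 15 absent from the compendium
  res <- screen_genes(comp, gene_list, th)
  expect_equal(attr(res, "n_informative"), 25)
  expect_equal(attr(res, "pct_informative"), 62.5)
  expect_true(all(res$passes[res$gene %in% elevated]))
  expect_false(any(res$passes[!res$informative]))
  expect_true(all(is.na(res$p_vs_pns[!res$informative])))
  # passing implies all three p-values below alpha
  pz <- res[res$passes, ]
  expect_true(all(pz$p_vs_nervous < 0.05 & pz$p_vs_pns < 0.05 &
                    pz$p_vs_all_healthy < 0.05))
})

test_that("null genes rarely pass the all-three-significant rule", {
  cfg <- sim_config(seed = 36, elevated_effect = 0)
  genes <- sprintf("NULLG%03d", 1:200)
  comp <- generate_compendium(25, genes, character(0), cfg)
  res <- screen_genes(comp, genes, th)
  # union bound: pass probability under the null is below 3 * alpha
  expect_lt(mean(res$passes), 3 * 0.05)
})

test_that("screen validates empty comparison groups", {
  cfg <- sim_config(seed = 37)
  comp <- generate_compendium(10, "G1", character(0), cfg)
  comp$annotations$tissue_class[comp$annotations$tissue_class ==
                                  "HEALTHY_PNS"] <- "HEALTHY_OTHER"
  expect_error(screen_genes(comp, "G1", th), "non-empty")
})

test_that("positive controls pass when planted and warn when absent or flat", {
  cfg <- sim_config(seed = 38, elevated_effect = 4)
  genes <- c("MYCN", "MEIS1", "ALK", sprintf("G%02d", 1:10))
  comp <- generate_compendium(30, genes, c("MYCN", "MEIS1", "ALK"), cfg)
  rep1 <- check_positive_controls(comp, c("MYCN", "MEIS1", "ALK"), th)
  expect_true(rep1$all_pass)
  expect_length(rep1$missing, 0)

  expect_warning(
    expect_warning(
      rep2 <- check_positive_controls(comp, c("MYCN", "ABSENT"), th),
      "absent"
    ),
    "not all positive controls"
  )
  expect_equal(rep2$missing, "ABSENT")
  expect_false(rep2$all_pass)

  # un-shifted controls should not all pass
  cfg0 <- sim_config(seed = 39, elevated_effect = 0)
  comp0 <- generate_compendium(30, genes, character(0), cfg0)
  expect_warning(rep3 <- check_positive_controls(comp0,
                                                 c("MYCN", "MEIS1", "ALK"),
                                                 th),
                 "not all positive controls")
  expect_false(rep3$all_pass)
})

test_that("activation ranking orders passing genes by planted effect size", {
  cfg <- sim_config(seed = 40)
  genes <- sprintf("G%02d", 1:20)
  comp <- generate_compendium(30, genes, character(0), cfg)
  # plant two different shifts directly
  nb <- comp$annotations$tissue_class == "NEUROBLASTOMA"
  comp$expression["G01", nb] <- comp$expression["G01", nb] + 3
  comp$expression["G02", nb] <- comp$expression["G02", nb] + 1
  res <- screen_genes(comp, genes, th)
  expect_true(all(res$passes[res$gene %in% c("G01", "G02")]))
  ranked <- rank_activation(res, comp)
  expect_equal(ranked$gene[1], "G01")
  # score agrees with an independent median computation
  healthy <- !nb
  for (i in seq_len(nrow(ranked))) {
    v <- comp$expression[ranked$gene[i], ]
    expect_equal(ranked$activation_score[i],
                 median(v[nb]) - median(v[healthy]))
  }
  expect_false(is.unsorted(rev(ranked$activation_score)))

  # no passing genes -> empty report
  none <- res; none$passes <- FALSE
  expect_equal(nrow(rank_activation(none, comp)), 0)
})
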