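#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators in one validated
#' object. The defaults encode the study conditions the pipeline is meant
#' to reproduce: a high-resolution oligo aCGH grid, additive Gaussian array
#' noise around a copy-neutral log2 baseline of 0, expression linearly
#' coupled to copy number, FISH cohorts in which 14/33 of tumors carry a
#' 12q24-style gain, 7/33 carry MYCN amplification and 1/33 carry both,
#' 20-60 scoreable nuclei per tumor, exponential survival with hazards
#' ordered 3:2:1 across MYCN-amplified / gained / neither groups, and a
#' +3 standard-deviation expression shift for planted tumor-elevated genes.
#'
#' @param seed integer seed governing all randomness of a generator call.
#' @param probe_spacing_bp distance between adjacent aCGH probes in bp.
#' @param noise_sd standard deviation of additive Gaussian noise on probe
#'   log2 ratios.
#' @param dosage_slope slope linking expression log2 ratio to the true copy
#'   number log2 ratio at the gene's position.
#' @param expression_noise_sd standard deviation of additive expression
#'   noise.
#' @param gain_prevalence,myc_prevalence,both_prevalence probabilities that
#'   a tumor carries the locus gain, MYCN amplification, or both. Must
#'   satisfy `both_prevalence <= min(gain_prevalence, myc_prevalence)` and
#'   `gain_prevalence + myc_prevalence - both_prevalence <= 1`.
#' @param nuclei_range integer pair: range of nuclei scored per tumor.
#' @param group_hazards named numeric vector of exponential hazard rates
#'   for risk groups `MYCN_AMP`, `GAIN_12Q24`, `NEITHER` (per unit of
#'   follow-up time).
#' @param censoring_rate probability that a tumor's follow-up is censored
#'   before the event.
#' @param elevated_effect location shift added to planted tumor-elevated
#'   genes in compendium tumor samples, in baseline-SD units.
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$gain_prevalence
#' @export
sim_config <- function(seed = 1L,
                       probe_spacing_bp = 10000L,
                       noise_sd = 0.2,
                       dosage_slope = 1,
                       expression_noise_sd = 0.5,
                       gain_prevalence = 14 / 33,
                       myc_prevalence = 7 / 33,
                       both_prevalence = 1 / 33,
                       nuclei_range = c(20L, 60L),
                       group_hazards = c(MYCN_AMP = 0.3, GAIN_12Q24 = 0.2,
                                         NEITHER = 0.1),
                       censoring_rate = 0.2,
                       elevated_effect = 3) {
  probs <- c(gain_prevalence, myc_prevalence, both_prevalence, censoring_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("prevalences and censoring_rate must lie in [0, 1]", call. = FALSE)
  }
  if (both_prevalence > min(gain_prevalence, myc_prevalence)) {
    stop("both_prevalence cannot exceed either marginal prevalence",
         call. = FALSE)
  }
  if (gain_prevalence + myc_prevalence - both_prevalence > 1) {
    stop("prevalences imply a negative share of unaltered tumors",
         call. = FALSE)
  }
  if (length(nuclei_range) != 2 || nuclei_range[1] < 1 ||
      nuclei_range[2] < nuclei_range[1]) {
    stop("nuclei_range must be an increasing pair with lower bound >= 1",
         call. = FALSE)
  }
  need <- c("MYCN_AMP", "GAIN_12Q24", "NEITHER")
  if (!all(need %in% names(group_hazards)) || any(group_hazards <= 0)) {
    stop("group_hazards must name positive rates for MYCN_AMP, GAIN_12Q24, NEITHER",
         call. = FALSE)
  }
  if (probe_spacing_bp <= 0) stop("probe_spacing_bp must be positive", call. = FALSE)
  if (noise_sd < 0 || expression_noise_sd < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      probe_spacing_bp = as.numeric(probe_spacing_bp),
      noise_sd = noise_sd,
      dosage_slope = dosage_slope,
      expression_noise_sd = expression_noise_sd,
      gain_prevalence = gain_prevalence,
      myc_prevalence = myc_prevalence,
      both_prevalence = both_prevalence,
      nuclei_range = as.integer(nuclei_range),
      group_hazards = group_hazards[need],
      censoring_rate = censoring_rate,
      elevated_effect = elevated_effect
    ),
    class = "sim_config"
  )
}

#' Generate a synthetic genome annotation and aCGH probe grid
#'
#' Lays out `n_genes` non-overlapping genes over `n_chromosomes` chromosomes
#' of equal length and an evenly spaced probe grid, the coordinate frame for
#' all other generators. Genes are distributed as evenly as possible across
#' chromosomes, each placed uniformly at random inside its own slot so
#' intervals never overlap and come out sorted by position.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param n_genes total number of genes.
#' @param seed integer seed; fixed seed gives identical output.
#' @param probe_spacing_bp probe grid spacing in bp.
#' @return A list with class `synthetic_genome`: `genes` (data frame with
#'   `gene_id`, `symbol`, `chromosome`, `start_bp`, `end_bp`, `strand`),
#'   `probe_positions` (data frame with `chromosome`, `position_bp`) and
#'   `chrom_length_bp`.
#' @examples
#' gen <- generate_genome(1, 1e6, 10, seed = 7)
#' head(gen$genes)
#' @export
generate_genome <- function(n_chromosomes, chrom_length_bp, n_genes, seed,
                            probe_spacing_bp = 10000L) {
  if (n_chromosomes < 1 || chrom_length_bp < 1 || n_genes < 1) {
    stop("n_chromosomes, chrom_length_bp and n_genes must be positive",
         call. = FALSE)
  }
  per_chrom <- ceiling(n_genes / n_chromosomes)
  if (chrom_length_bp < 2 * per_chrom) {
    stop("chromosomes too short to hold the requested genes", call. = FALSE)
  }
  with_seed(seed, {
    chrom_of <- rep(seq_len(n_chromosomes), length.out = n_genes)
    chrom_of <- sort(chrom_of)
    genes <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ci) {
      k <- sum(chrom_of == ci)
      if (k == 0) return(NULL)
      # one slot per gene; gene occupies a random sub-interval of its slot
      slot <- floor(chrom_length_bp / k)
      start <- integer(k); end <- integer(k)
      for (i in seq_len(k)) {
        lo <- (i - 1) * slot + 1
        hi <- i * slot
        len <- max(1L, floor(stats::runif(1, 0.05, 0.5) * slot))
        s <- floor(stats::runif(1, lo, hi - len + 1))
        start[i] <- s
        end[i] <- min(s + len - 1, hi)
      }
      data.frame(
        chromosome = sprintf("chr%d", ci),
        start_bp = start, end_bp = end,
        stringsAsFactors = FALSE
      )
    }))
    genes$gene_id <- sprintf("SIMG%05d", seq_len(nrow(genes)))
    genes$symbol <- sprintf("G%d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes <- genes[, c("gene_id", "symbol", "chromosome", "start_bp",
                       "end_bp", "strand")]
    probes <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ci) {
      pos <- seq(1, chrom_length_bp, by = probe_spacing_bp)
      data.frame(chromosome = sprintf("chr%d", ci), position_bp = pos,
                 stringsAsFactors = FALSE)
    }))
    structure(
      list(genes = genes, probe_positions = probes,
           chrom_length_bp = chrom_length_bp,
           probe_spacing_bp = as.numeric(probe_spacing_bp)),
      class = "synthetic_genome"
    )
  })
}

#' Plant copy-number segments
#'
#' Convenience constructor for the ground-truth segment table consumed by
#' [generate_cgh_profile()] and [generate_expression()].
#'
#' @param chromosome,start_bp,end_bp,true_log2 equal-length vectors giving
#'   each planted segment's location and its log2 copy-number level.
#' @return A data frame with one row per segment.
#' @export
planted_segments <- function(chromosome, start_bp, end_bp, true_log2) {
  seg <- data.frame(chromosome = as.character(chromosome),
                    start_bp = as.numeric(start_bp),
                    end_bp = as.numeric(end_bp),
                    true_log2 = as.numeric(true_log2),
                    stringsAsFactors = FALSE)
  if (any(seg$start_bp > seg$end_bp)) {
    stop("planted segments need start_bp <= end_bp", call. = FALSE)
  }
  for (ch in unique(seg$chromosome)) {
    s <- seg[seg$chromosome == ch, ]
    s <- s[order(s$start_bp), ]
    if (nrow(s) > 1 && any(s$start_bp[-1] <= s$end_bp[-nrow(s)])) {
      stop("planted segments overlap on ", ch, call. = FALSE)
    }
  }
  seg
}

# true log2 copy-number level at arbitrary positions given planted segments
true_log2_at <- function(chromosome, position_bp, planted) {
  out <- numeric(length(position_bp))
  if (is.null(planted) || nrow(planted) == 0) return(out)
  for (i in seq_len(nrow(planted))) {
    hit <- chromosome == planted$chromosome[i] &
      position_bp >= planted$start_bp[i] & position_bp <= planted$end_bp[i]
    out[hit] <- planted$true_log2[i]
  }
  out
}

#' Generate a synthetic aCGH profile
#'
#' Probe log2 ratio = level of the covering planted segment (0 where no
#' segment covers the probe, i.e. copy-neutral) plus additive Gaussian noise
#' of standard deviation `config$noise_sd`.
#'
#' @param genome a `synthetic_genome` from [generate_genome()].
#' @param planted data frame of planted segments ([planted_segments()]),
#'   or `NULL` for a flat profile.
#' @param config a [sim_config()].
#' @return A data frame of probes: `probe_id`, `chromosome`, `position_bp`,
#'   `log2_ratio`, sorted by chromosome and position.
#' @export
generate_cgh_profile <- function(genome, planted, config) {
  stopifnot(inherits(genome, "synthetic_genome"), inherits(config, "sim_config"))
  probes <- genome$probe_positions
  if (!is.null(planted) && nrow(planted) > 0) {
    if (!all(planted$chromosome %in% probes$chromosome)) {
      stop("planted segment on a chromosome absent from the genome",
           call. = FALSE)
    }
    if (any(planted$start_bp < 1 | planted$end_bp > genome$chrom_length_bp)) {
      stop("planted segment outside chromosome bounds", call. = FALSE)
    }
  }
  with_seed(config$seed, {
    truth <- true_log2_at(probes$chromosome, probes$position_bp, planted)
    lr <- truth
    if (config$noise_sd > 0) {
      lr <- lr + stats::rnorm(nrow(probes), 0, config$noise_sd)
    }
    out <- data.frame(
      probe_id = sprintf("P%06d", seq_len(nrow(probes))),
      chromosome = probes$chromosome,
      position_bp = probes$position_bp,
      log2_ratio = lr,
      stringsAsFactors = FALSE
    )
    out[order(out$chromosome, out$position_bp), , drop = FALSE]
  })
}

#' Generate dosage-coupled expression data
#'
#' One expression probe set per gene: log2 expression ratio =
#' `dosage_slope` x true copy-number log2 at the gene midpoint + Gaussian
#' noise. This is the planted dosage effect the integration stage is meant
#' to recover.
#'
#' @param genome a `synthetic_genome`.
#' @param planted the planted copy-number segments (the ground truth used
#'   for the aCGH profile).
#' @param config a [sim_config()]; `seed` is offset internally so profiles
#'   and expression built from the same config are independent draws.
#' @return A data frame: `probe_set_id`, `gene_id`, `chromosome`,
#'   `position_bp` (gene midpoint), `log2_ratio`.
#' @export
generate_expression <- function(genome, planted, config) {
  stopifnot(inherits(genome, "synthetic_genome"), inherits(config, "sim_config"))
  g <- genome$genes
  mid <- floor((g$start_bp + g$end_bp) / 2)
  with_seed(config$seed + 1L, {
    truth <- true_log2_at(g$chromosome, mid, planted)
    expr <- config$dosage_slope * truth
    if (config$expression_noise_sd > 0) {
      expr <- expr + stats::rnorm(nrow(g), 0, config$expression_noise_sd)
    }
    data.frame(
      probe_set_id = sprintf("%s_at", g$gene_id),
      gene_id = g$gene_id,
      chromosome = g$chromosome,
      position_bp = mid,
      log2_ratio = expr,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a FISH cohort with survival follow-up
#'
#' Each tumor draws a latent alteration group (both / gain-only / MYCN-only
#' / neither) from the configured prevalences. Nucleus-level signal counts
#' model discrete per-cell copy numbers with probe dropout: every nucleus
#' carries 2 centromere copies, and 2 test copies in un-gained tumors or
#' 3-4 test copies in gained tumors (the per-tumor mix of 3- and 4-copy
#' cells is drawn so tumor-level true ratios spread over 1.6-1.8, mean
#' 1.7, comfortably separated from the 1.5 gain cutoff); each copy is
#' detected with probability `detection_prob`, so counts are binomial and
#' the test/centromere ratio of means is unbiased for the true copy ratio.
#' Survival is exponential with the group hazard (MYCN-amplified worst,
#' gained intermediate, neither best); with probability `censoring_rate`
#' follow-up ends at a uniform fraction of the event time.
#'
#' @param n_tumors cohort size.
#' @param config a [sim_config()].
#' @param detection_prob per-copy probe detection probability (default
#'   0.95; hybridization dropout).
#' @return A list with class `fish_simulation`: `nuclei` (long data frame:
#'   `tumor_id`, `nucleus_id`, `test_count`, `centromere_count`),
#'   `annotations` (`tumor_id`, `myc_amplified`, `true_group`,
#'   `true_ratio`) and `survival` (`patient_id`, `time`, `event`).
#' @export
generate_fish_cohort <- function(n_tumors, config, detection_prob = 0.95) {
  stopifnot(inherits(config, "sim_config"))
  if (n_tumors < 1) stop("n_tumors must be >= 1", call. = FALSE)
  if (detection_prob <= 0 || detection_prob > 1) {
    stop("detection_prob must lie in (0, 1]", call. = FALSE)
  }
  p_both <- config$both_prevalence
  p_gain_only <- config$gain_prevalence - p_both
  p_myc_only <- config$myc_prevalence - p_both
  p_neither <- 1 - p_both - p_gain_only - p_myc_only
  with_seed(config$seed + 2L, {
    grp <- sample(c("both", "gain_only", "myc_only", "neither"), n_tumors,
                  replace = TRUE,
                  prob = c(p_both, p_gain_only, p_myc_only, p_neither))
    gained <- grp %in% c("both", "gain_only")
    myc <- grp %in% c("both", "myc_only")
    # gained tumors: mix of 3- and 4-copy cells; four_copy_frac in
    # (0.2, 0.6) puts the true ratio in 1.6-1.8 with mean 1.7
    four_copy_frac <- ifelse(gained, stats::runif(n_tumors, 0.2, 0.6), 0)
    ratio <- ifelse(gained, (3 + four_copy_frac) / 2, 1)
    n_nuc <- sample(seq(config$nuclei_range[1], config$nuclei_range[2]),
                    n_tumors, replace = TRUE)
    tumor_id <- sprintf("T%04d", seq_len(n_tumors))
    total <- sum(n_nuc)
    test_copies <- ifelse(rep(gained, times = n_nuc),
                          3L + stats::rbinom(total, 1L,
                                             rep(four_copy_frac, times = n_nuc)),
                          2L)
    nuclei <- data.frame(
      tumor_id = rep(tumor_id, times = n_nuc),
      nucleus_id = sequence(n_nuc),
      test_count = stats::rbinom(total, test_copies, detection_prob),
      centromere_count = stats::rbinom(total, 2L, detection_prob),
      stringsAsFactors = FALSE
    )
    risk <- ifelse(myc, "MYCN_AMP", ifelse(gained, "GAIN_12Q24", "NEITHER"))
    haz <- config$group_hazards[risk]
    t_event <- stats::rexp(n_tumors, rate = haz)
    censored <- stats::runif(n_tumors) < config$censoring_rate
    time <- ifelse(censored, t_event * stats::runif(n_tumors), t_event)
    structure(
      list(
        nuclei = nuclei,
        annotations = data.frame(tumor_id = tumor_id, myc_amplified = myc,
                                 true_group = grp, true_ratio = ratio,
                                 stringsAsFactors = FALSE),
        survival = data.frame(patient_id = tumor_id, time = time,
                              event = !censored, stringsAsFactors = FALSE)
      ),
      class = "fish_simulation"
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate an expression compendium with tissue classes
#'
#' Simulates the compendium used by the in silico screen: per-gene baseline
#' expression Normal(8, 1) in every tissue class, with `elevated_effect`
#' (in SD units) added to the tumor class on the planted elevated genes
#' only. Genes in `gene_list` absent from `compendium_genes` are simply not
#' measured, emulating array-generation gaps.
#'
#' @param n_per_class named integer vector of sample counts, names from
#'   `NEUROBLASTOMA`, `HEALTHY_PNS`, `HEALTHY_CNS`, `HEALTHY_OTHER`; a
#'   single unnamed number is recycled to all four classes.
#' @param compendium_genes character vector of genes measured in the
#'   compendium.
#' @param elevated_genes subset of `compendium_genes` planted as elevated
#'   in the tumor class.
#' @param config a [sim_config()].
#' @return A list with class `compendium`: `expression` (genes x samples
#'   numeric matrix) and `annotations` (`sample_id`, `tissue_class`).
#' @export
generate_compendium <- function(n_per_class, compendium_genes, elevated_genes,
                                config) {
  stopifnot(inherits(config, "sim_config"))
  classes <- c("NEUROBLASTOMA", "HEALTHY_PNS", "HEALTHY_CNS", "HEALTHY_OTHER")
  if (length(n_per_class) == 1 && is.null(names(n_per_class))) {
    n_per_class <- stats::setNames(rep(n_per_class, 4), classes)
  }
  if (!all(classes %in% names(n_per_class))) {
    stop("n_per_class must cover all four tissue classes", call. = FALSE)
  }
  if (any(n_per_class[classes] < 1)) {
    stop("every tissue class needs at least one sample", call. = FALSE)
  }
  if (!all(elevated_genes %in% compendium_genes)) {
    stop("elevated_genes must be a subset of compendium_genes", call. = FALSE)
  }
  with_seed(config$seed + 3L, {
    cls <- rep(classes, times = n_per_class[classes])
    n <- length(cls)
    sample_id <- sprintf("S%04d", seq_len(n))
    m <- matrix(stats::rnorm(length(compendium_genes) * n, mean = 8, sd = 1),
                nrow = length(compendium_genes),
                dimnames = list(compendium_genes, sample_id))
    nb <- cls == "NEUROBLASTOMA"
    if (length(elevated_genes) > 0 && any(nb)) {
      m[elevated_genes, nb] <- m[elevated_genes, nb] + config$elevated_effect
    }
    structure(
      list(expression = m,
           annotations = data.frame(sample_id = sample_id, tissue_class = cls,
                                    stringsAsFactors = FALSE)),
      class = "compendium"
    )
  })
}
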