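---
title: "Integrative amplicon screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative amplicon screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliseek)
```

`ampliseek` chains four analyses that together move from a raw aCGH
profile to a short, clinically anchored list of candidate amplicon driver
genes. This vignette explains the model behind each stage, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the design decisions taken where the methodology left room.

## 1. Amplicon calling by thresholding

The copy-number model is deliberately minimal: a probe's log2 ratio is
the log2 of tumor-to-reference copy number plus noise, and calling is a
pure threshold rule with no smoothing or change-point segmentation (no
CBS, no HMM). Amplicons of interest here are high-amplitude events —
log2 ratios of 2 or more, i.e. at least a four-fold increase — which sit
far above array noise, so thresholding is both sufficient and exactly
reproducible.

Cutoffs (see `analysis_thresholds()`):

* `amp_log2 = 2`, `high_amp_log2 = 3.5` — amplification and high-level
  amplification, strictly-greater comparisons.
* `loss_log2 = -1` — loss. The conventional hemizygous-loss rule is a
  *linear* ratio below 0.5, which is log2 < −1; a stated cutoff of
  "ratio < 0.5" applied literally on the log2 scale would include the
  copy-neutral baseline at 0, so the linear reading is the default and
  the literal one remains available by configuration.
* `min_probes = 2` — segments need at least two qualifying probes.
  Two-probe microamplifications (the scale of a single focal oncogene
  such as ALK at 2p23) are kept; isolated single-probe outliers, the
  most common array artifact, are not.
* `max_gap_probes = 0` — no bridging of interior non-qualifying probes
  by default, since nothing in the underlying methodology describes gap
  tolerance. A run containing both `AMP` and `HIGH_AMP` probes reports
  once as `HIGH_AMP`, matching the convention of one amplicon per locus.

Coordinates are 1-based inclusive bp; megabase region strings divide by
1e6 and round half-up to one decimal ("14.7-16.0 Mb").

## 2. Dosage integration

The dosage model says expression log2 ratios track copy-number log2
ratios. The integration has three steps, each with a fixed, documented
convention:

* **Position.** A probe set mapping to an annotated gene sits at the
  gene-interval midpoint (rounded down) — the midpoint minimises the
  worst-case distance to any transcript probe. Unmapped probe sets fall
  back to the array vendor's position; probe sets with neither are
  excluded and counted. Multiple probe sets per gene are integrated
  independently, with no collapsing.
* **Copy number.** The median log2 ratio of aCGH oligos within 50 kb of
  the assigned position, with the window closed at exactly 50,000 bp.
  Median rather than mean keeps a single discordant oligo from moving
  the gene's copy number. No qualifying oligo means no copy number
  (reported, excluded from bins).
* **Expression call.** The top and bottom `k = floor(N × 7/100)` ratios
  in a sample are `OVER`/`UNDER`. The percentile is a set-size rule, not
  an interpolated quantile, so call counts are exact and symmetric by
  construction. Ties at the boundary are resolved by a stable ascending
  sort with probe-set identifier as tie-break — deterministic across
  runs. Calls are computed over *all* records in the sample before
  position mapping (configurable), since the percentile describes the
  sample's expression distribution, not the mappable subset.

The bin-frequency analysis divides genes by copy number into half-open
bins `(lower, upper]` and plots the fraction of `OVER`/`UNDER` calls per
bin. Default interior edges −1, −0.5, 0.5, 1, 2, 3.5 align with the
calling thresholds; the exact published bin boundaries are not printed
anywhere, so these defaults are a documented choice.

## 3. FISH scoring and survival stratification

A tumor's gain score is the mean test-probe count over all scored nuclei
divided by the mean centromere count — the ratio of means, not the mean
of per-nucleus ratios, so occasional zero-centromere nuclei do not
produce infinities. Gain is a ratio ≥ 1.5, inclusive: a stated 1.5-fold
increase "considered as gain" includes the stated value. Tumors with
fewer than 20 or more than 60 scored nuclei, or no centromere signal,
are marked non-informative and drop out of denominators rather than
raising errors — which is why cohort percentages are reported "x of n
informative".

Crosstab percentages round half-up to whole percent, matching clinical
reporting (14 of 33 prints as 42%). Association between locus gain and
MYCN amplification uses the plain Pearson chi-square (no Yates
correction by default; configurable).

Risk groups order as MYCN-amplified, then locus-gained, then neither.
The rare tumor carrying both alterations is assigned to the
MYCN-amplified group: MYCN amplification is the established
worst-prognosis marker, so the clinically dominant label wins. This is
configurable (`myc_dominates = FALSE`) because the placement is a
convention, not a fact.

Kaplan–Meier estimation and the k-sample log-rank test are delegated to
the `survival` package (`survfit`, `survdiff`); ties follow the standard
convention that events precede censorings at the same time, and the
log-rank variance is the hypergeometric form with a generalised inverse
when singular. The test suite independently re-derives the product-limit
curve by hand and checks the log-rank p-value against a permutation
null, so the delegation is verified, not assumed. Cox regression for
confounder adjustment is deliberately out of scope; covariates pass
through untouched.

## 4. The in silico screen

For each amplicon gene, three one-sided Mann–Whitney–Wilcoxon rank-sum
tests ask whether tumor expression is stochastically greater than (i)
healthy nervous system samples (peripheral ∪ central), (ii) healthy
peripheral nervous system samples, and (iii) all healthy samples. The
one-sided alternative is the screen's question — activation, not mere
difference — and a two-sided option exists for sensitivity analyses.

A gene passes only when all three raw p-values fall below α = 0.05. No
multiple-testing correction is applied by default: the all-three-pass
rule is itself conservative (its null pass probability is bounded by the
smallest of the three marginal levels), and screens of this kind report
raw per-comparison p-values. A Bonferroni option exists. Expect roughly
α-level false positives among null genes — on 20 null genes about one
will pass by chance — which is the honest operating characteristic of
the published rule, not a defect to tune away.

`mww_rank_sum()` uses the exact null distribution when the sample-size
product is at most 400 and the pooled data are tie-free; beyond that it
uses the normal approximation with tie-corrected variance and continuity
correction. The branch boundary was checked empirically: exact and
approximate p-values agree within 0.01 there.

Positive controls (e.g. MYCN, MEIS1, ALK) run through the same screen;
failing controls raise a warning rather than an error, because a screen
whose known oncogenes do not light up is underpowered, not broken.
Passing genes rank by the difference between the tumor median and the
all-healthy median — a transparent effect-size stand-in for "strongest
activation", for which no formal published criterion exists — with ties
broken by the smaller p-value against all healthy samples.

## The synthetic-data generator

The generator produces every input with planted ground truth, under
defaults chosen once to mirror the study conditions:

* **aCGH.** Evenly spaced probes (10 kb default), copy-neutral baseline
  log2 = 0, additive Gaussian noise (SD 0.2 default — typical
  oligo-array scatter), planted segments with exact levels. With zero
  noise every planted segment is exactly reconstructible from the
  probes, which the recovery tests exploit.
* **Expression.** One probe set per gene, log2 ratio =
  slope × true copy log2 at the gene midpoint + Gaussian noise
  (slope 1, SD 0.5 default). One-probe-set-per-gene keeps truth tables
  unambiguous; many-to-one mapping is exercised via explicit fixtures
  instead.
* **FISH.** Latent per-tumor groups drawn at prevalences 14/33 gained,
  7/33 MYCN-amplified, 1/33 both — the published cohort composition.
  Nucleus counts model discrete per-cell copy numbers with binomial
  probe detection (p = 0.95): two centromere copies everywhere, two
  test copies in un-gained tumors, and a per-tumor mix of three- and
  four-copy cells in gained tumors spreading true ratios over 1.6–1.8
  with mean 1.7 — the observed mean ratio in gained tumors. A Poisson
  count model was considered and rejected: at 20–60 nuclei it gives the
  per-tumor ratio a standard error near 0.24, misclassifying roughly a
  fifth of gained tumors below the 1.5 cutoff, whereas real FISH counts
  concentrate tightly on the modal signal number with occasional
  dropout. Detection efficiency cancels in the ratio of means, so the
  score is unbiased for the true copy ratio.
* **Survival.** Exponential event times with hazards 0.3 / 0.2 / 0.1
  for MYCN-amplified / gained / neither (the 3:2:1 ordering that makes
  log-rank power predictable); censoring replaces the event with a
  uniform fraction of its time at the configured rate (0.2 default).
* **Compendium.** Baseline expression Normal(8, 1) in four tissue
  classes; planted elevated genes get +3 SD in tumor samples. Missing
  array-generation coverage is emulated simply as genes absent from the
  compendium matrix.

What the generator does **not** emulate: GC waves and spatial artifacts
on arrays, MAS5/RMA preprocessing, intratumoral heterogeneity of FISH
counts beyond the two-level copy mix, non-proportional hazards, batch
structure across array generations, and correlated expression between
genes. Passing tests therefore demonstrate that the pipeline's logic and
arithmetic recover planted truth under clean generative assumptions —
not that the thresholds are optimal for any particular real dataset.

## Numerical conventions and problem sizes

Reported percentages round half away from zero (matching "14 of 33 =
42%"); `round()`'s banker's rounding would print 38.5 as 38. Degenerate
inputs fail loudly: empty cohorts, unsorted probes, non-positive
intensities, impossible prevalence combinations. Probabilistic tests are
calibrated against exact binomial 99% acceptance bands rather than
point equality; determinism tests require byte-identical serialized
output for a fixed seed.

The test and verification runs use deliberately modest problem sizes —
profiles of a few hundred to a few thousand probes, 500-tumor simulated
cohorts, 200-replicate calibration loops, compendia of tens of samples
per class — which are comfortably beyond the sizes where the asymptotic
approximations engage and keep the whole suite fast enough to run on
every change.

## Known limitations

* Threshold calling cannot see low-amplitude events close to the noise
  floor; it is intentionally restricted to high-amplitude amplicons and
  clear losses, with FISH as the instrument for low-level gain.
* The 50-kb window uses the probe-set's single assigned position; genes
  longer than the window can draw copy number from only part of their
  extent.
* Percentile expression calls are relative to the sample itself — a
  genome-wide dosage shift (e.g. near-tetraploidy) would recalibrate
  what "overexpressed" means.
* The activation ranking is a median-difference heuristic; with heavily
  skewed expression in a tumor subset, inspecting the per-gene
  distributions remains essential.
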