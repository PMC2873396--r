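# ampliseek

Integrative copy-number, expression and tissue screening for amplicon
driver genes.

## The problem

Focal DNA amplicons in tumors often carry the genes that drive
progression, but a copy-number profile alone cannot say which amplified
gene matters clinically. `ampliseek` implements a complete
discovery-to-validation chain for neuroblastoma-style studies:

1. **Amplicon calling from aCGH.** Probe-level log2 copy-number ratios
   are thresholded — amplification at log2 ratio > 2, high-level
   amplification at > 3.5, loss at log2 ratio < −1 (linear ratio < 0.5) —
   and contiguous altered probes are merged into reported segments, down
   to two-probe microamplifications.
2. **Dosage integration.** Each expression probe set is placed at its
   gene's genomic midpoint, assigned the median log2 ratio of aCGH oligos
   within 50 kb, and called over/underexpressed when its expression log2
   ratio falls in the top/bottom 7% of its sample. Binning genes by copy
   number shows how the frequency of overexpression rises with dosage,
   and the intersection — amplified *and* overexpressed — is the
   candidate driver list.
3. **FISH validation on tissue.** Per-tumor test/centromere signal
   ratios from 20–60 scored nuclei call locus gain at a ratio ≥ 1.5.
   The cohort is cross-tabulated against MYCN amplification (Pearson
   chi-square) and stratified into three risk groups — MYCN-amplified /
   locus-gained / neither — compared by Kaplan–Meier curves and the
   k-sample log-rank test.
4. **In silico screening.** Each amplicon gene is tested for elevated
   tumor expression against three healthy compendium groupings (nervous
   system, peripheral nervous system, all healthy) with one-sided
   Mann–Whitney–Wilcoxon rank-sum tests; a gene passes only when all
   three raw p-values fall below 0.05, and passing genes are ranked by
   the tumor-vs-healthy median difference.

A synthetic-data module generates every input with planted ground truth
(amplicon coordinates, dosage slopes, FISH gain prevalences, survival
hazards, elevated genes), so the whole pipeline is testable end to end
without any external download.

## Worked example

```r
library(ampliseek)
th <- analysis_thresholds()

# plant a high-level amplicon at 14.7-16.0 Mb and call it back
gen <- generate_genome(1, 3e7, 100, seed = 1)
truth <- planted_segments("chr1", 14700001, 16000000, true_log2 = 4)
profile <- generate_cgh_profile(gen, truth, sim_config(seed = 1, noise_sd = 0.1))
call_segments(profile, th)
#> CNV segments: 1 region(s)
#>  chromosome start_bp   end_bp locus_class n_probes median_log2       region
#>        chr1 14700001 15990001    HIGH_AMP      130    4.000173 14.7-16.0 Mb

# score a FISH cohort and stratify survival
fc  <- generate_fish_cohort(500, sim_config(seed = 2))
coh <- score_fish_cohort(fc$nuclei, fc$annotations)
fish_crosstab(coh)
#> FISH cohort crosstab (500 informative tumor(s))
#>   gained: 40%   MYCN-amplified: 22%   either: 59%
#>   gained tumors also MYCN-amplified: 9%
#>   counts: both=17  gain_only=182  myc_only=94  neither=207

rec <- merge(coh, fc$survival, by.x = "tumor_id", by.y = "patient_id")
stratify_survival(rec)
#> Risk stratification
#>   group sizes: GAIN_12Q24=182  MYCN_AMP=111  NEITHER=207
#> Log-rank test: chi-square = 100.469 on 2 df, p = 1.526e-22
```

The crosstab recovers the planted gain prevalence (40% scored vs 42%
planted, within sampling noise), and the log-rank test separates the three risk groups whose
simulated hazards are ordered MYCN-amplified > gained > neither.

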