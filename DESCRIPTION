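Package: ampliseek
Title: Integrative Copy-Number, Expression and Tissue Screening for
    Amplicon Driver Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for locating clinically relevant
    copy-number-driven genes in neuroblastoma and similar tumors. Calls
    amplicons and losses from array-CGH log2 ratio profiles by thresholding,
    joins expression probe sets to copy number through a 50-kb windowed
    median with percentile-based over/underexpression calls and
    copy-number-bin frequency summaries, scores locus gain from nucleus-level
    FISH signal counts with a 1.5-fold ratio rule and cross-tabulates it
    against MYCN amplification, stratifies survival into three risk groups
    with Kaplan-Meier estimation and the log-rank test, and screens amplicon
    genes for tumor-elevated expression against healthy tissue compendia
    with one-sided Mann-Whitney-Wilcoxon rank-sum tests. Ships a synthetic
    data generator that plants known amplicons, dosage effects, FISH gain
    groups and elevated genes so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
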