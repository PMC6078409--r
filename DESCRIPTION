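Package: lfqnest
Title: Label-Free Quantitative Proteomics Differential Analysis with Nested Replicates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Differential-abundance analysis for label-free quantification (LFQ)
    proteomics experiments with nested technical and biological replicates, as
    used for comparing injury responses of fetal and adult cartilage secretomes.
    Implements decoy/contaminant and minimum-identification filtering, global
    epsilon imputation of left-censored missing values, mean log-shift
    normalization, per-protein generalized least squares with a consensus
    within-block correlation, second-level (difference-of-differences)
    contrasts, empirical-Bayes moderated t-statistics, Benjamini-Yekutieli FDR
    control, a four-test Venn decomposition of significant protein sets, and
    Spearman sample-correlation summaries with correlation-ellipse glyphs.
    Includes a synthetic-data generator that emulates the 2x2 nested design
    with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
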