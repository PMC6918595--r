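Package: itraqdep
Title: Differential Expression Pipeline for Isobaric Reporter-Ion Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for differential protein expression analysis
    of multiplexed isobaric-label (iTRAQ/TMT) experiments, starting from
    filtered peptide-spectrum-match (PSM) reporter-ion tables. Implements
    identification filtering (ion score, PSM-level FDR), unique-peptide
    median-ratio protein rollup, per-replicate fold changes combined by
    geometric mean, protein-level two-tailed t-tests on within-spectrum log2
    ratios, dual-threshold differential expression calling, two-tailed Fisher
    exact term enrichment against the quantified background, cross-contrast
    overlap and direction-concordance analysis, and orthogonal-validation
    statistics (densitometry normalization with ANOVA, fold-change
    correlation, fetal-loss arithmetic). Includes a spike-in simulator that
    generates PSM tables, annotation maps, densitometry and fetal-count
    tables with ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
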