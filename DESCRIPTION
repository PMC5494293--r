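Package: gcfmir
Title: Two-Stage qPCR miRNA Panel Analysis for Gingival Crevicular Fluid
Version: 1.0.0
Authors@R:
    person("GCF", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantitation-cycle (Cq) matrices from
    PCR-based miRNA panels profiled in gingival crevicular fluid and similar
    low-input biofluids. Implements the two-stage biomarker workflow used in
    periodontitis studies: detection filtering with right-censoring at 40
    cycles, global-mean normalization for dense discovery panels,
    pairwise-stability (M value) reference-miRNA selection with iterative
    exclusion and multi-reference normalization for focused validation panels,
    per-miRNA delta-delta-Cq differential statistics with Benjamini-Hochberg
    FDR control, candidate panel selection, discovery-versus-validation
    direction concordance with Spearman rank correlation, matched-pair
    comparisons, list overlaps, PCA and hierarchical clustering summaries, and
    a seeded synthetic Cq-data generator with known ground truth for
    end-to-end testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
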