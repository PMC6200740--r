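Package: rzscreen
Title: Robust Z-Score Drug-Screening Signatures and Disease-Signature
    Reversal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for plate-structured transcriptomic drug
    screens of the L1000 type, run side by side in induced neural progenitor
    cells and cancer cell lines. Converts plate-annotated log2 expression
    matrices into per-drug, per-cell-line robust Z-score (RZS) signatures
    against plate- and cell-matched vehicle wells; calls threshold-based
    differential expression and cross-group differential responses; tests
    gene-set regulation between cell groups with a two-sample t approach and
    FDR control; scores drugs for reversal of a disease expression signature
    with a Kolmogorov-Smirnov connectivity statistic and permutation FDR;
    tests chemogenomic feature over-representation among set-regulating drugs
    with class-specific backgrounds; and scans transcripts and variant windows
    for degenerate RNA-binding motifs with density and cohort enrichment
    tests. A synthetic-screen generator with planted ground truth (batch
    effects, cell-type and diagnosis dependent drug effects, signature
    reversers, motif densities, variant cohorts) makes every stage testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
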