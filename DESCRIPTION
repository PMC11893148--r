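Package: diaquant
Title: Downstream Analysis of DIA Mass-Spectrometry Precursor Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standardized downstream analysis pipeline for long-format
    precursor-level quantification reports from data-independent acquisition
    (DIA) mass spectrometry. Covers report ingestion and validation,
    identification-rate summaries, q-value and oxidized-methionine filtering,
    condition-wise completeness filtering, log2 median normalization,
    batch/covariate adjustment of peptide intensities, protein quantification
    by iBAQ (with in-silico tryptic digestion), Hi3/Top3 and MaxLFQ
    (pairwise-ratio least squares), peptide-centric differential statistics
    (plain and empirical-Bayes moderated t-tests aggregated to proteins by the
    PECA median-p order-statistic rule), multivariate QC (PCA, sample
    correlation, CV, ON/OFF presence-absence calls), annotated result tables
    with a two-dimensional iBAQ-decile color code, and a self-contained HTML
    report. A fully deterministic synthetic-study generator with known ground
    truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
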