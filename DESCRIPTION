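Package: fuccitrack
Title: Cell-Cycle Phase Timing from FUCCI Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless analysis pipeline for dual-channel FUCCI
    (fluorescent ubiquitination-based cell cycle indicator) time-lapse
    movies: adaptive-threshold nucleus segmentation, click-scripted
    lineage tracking across the dark mitosis-to-G1 gap, extraction of
    per-cell red/green intensity traces, and conversion of those traces
    into G1 and S/G2/M phase durations with censoring. Includes genotype
    comparison statistics (exact and tie-corrected Mann-Whitney U,
    Bonferroni correction, boxplot summaries), ancillary quantitative
    assays (propidium-iodide DNA-content gating, 2^-ddCt relative
    expression, ROI intensity quantification), CRISPR single-allele
    genotyping, and a synthetic-data module that simulates FUCCI movies
    and assay fixtures with exported ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    withr,
    survival,
    EBImage,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
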