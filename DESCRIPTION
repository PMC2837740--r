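Package: anro
Title: Analysis of Array-Based Nuclear Run-On Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalization, Z-ratio differential expression and downstream
    analysis for paired nascent (nuclear run-on) and total RNA microarray
    time courses. Implements detection-score filtering, per-array Z-score
    normalization of log10 intensities, Z-ratio statistics with
    Benjamini-Hochberg false discovery control and the compound
    p/FDR/fold/Z-ratio significance filter, first-appearance transcriptional
    wave assignment with nascent-vs-total lead-lag summaries, parametric
    gene-set enrichment (PAGE) across matrices of contrasts with GMT input
    and output, complete-linkage clustering under the uncentered Pearson
    similarity, cross-platform joining and concordance of log-ratios, and
    intersection with ChIP binding lists to call direct transcription-factor
    targets. A seeded synthetic-data module emulates a Myc-induction
    experiment with planted transcriptional waves so every stage is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
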