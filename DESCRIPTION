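Package: riboseek
Title: Screening and Translational Profiling of Tissue-Specific
    Ribosome-Associated Long Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for nominating tissue-specific long
    noncoding RNAs from multi-organ expression matrices and profiling
    their translational biology.  Implements a cross-species specificity
    screen (expression fold-filter, annotation, ortholog and
    cross-species validation stages), classification of ribosome
    association from polysome-profiling fractions, nuclear/cytoplasmic
    localization from single-molecule FISH spot counts and fractionation
    qPCR, conserved promoter-window detection with position-weight-matrix
    motif scanning and an exact dynamic-programming null, time-course
    peak comparison between ribosome-protected and total RNA, robust-z
    footprint stall-site detection, and ribosome-stalling-motif
    enrichment statistics (exact and tie-corrected Mann-Whitney U,
    category chi-square with Monte-Carlo fallback).  A deterministic
    synthetic-data module generates every input with known ground truth
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
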