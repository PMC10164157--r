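Package: combscreen
Title: Analysis and Simulation of Combinatorial CRISPR Dropout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Quantification and analysis of dual-cassette (combinatorial and
    orthogonal) CRISPR knockout screens read out by paired-guide sequencing.
    Provides anchored spacer extraction and bounded-mismatch matching of
    paired-end reads against a designed combination library,
    library-uniformity quality control (Lorenz curves, P90/P10 skew),
    normalization to sequencing depth and the median of non-targeting
    control combinations, guide-pair and median-aggregated gene-pair log2
    fold changes, effect-size-range and class-separation statistics,
    single-guide decomposition via non-targeting partners, and ROC/AUC
    benchmarking of essential-gene and tumor-suppressor recovery against a
    dependency-score gold standard. A configurable simulator with known
    ground truth (per-gene fitness, per-guide activity, per-design
    RNA-processing penalties, multinomial sequencing noise) emulates such
    screens end to end, down to raw paired FASTQ reads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
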