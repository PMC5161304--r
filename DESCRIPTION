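Package: nmiscan
Title: Spectrum-Kernel SVM Prediction of Non-Methylated Islands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide prediction of non-methylated islands (NMIs) from DNA
    sequence using a spectrum-kernel support vector machine. Provides interval
    and FASTA/BED input-output, preprocessing of genomes into labeled
    fixed-width windows (mappability masking, NMI border exclusion, tiling and
    coverage-based labeling), sparse k-mer spectrum features with exact
    feature-weight extraction from the SVM dual solution, classical CpG-island
    baselines (observed/expected CpG ratio and the UCSC running-score island
    caller), imbalance-aware ROC/PR evaluation on 50 bp windows, experiment
    drivers for grid-search tuning, shuffled-label controls and cross-species
    model transfer, and a synthetic-genome generator with planted warm- or
    cold-blooded style islands for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Matrix,
    kernlab,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
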