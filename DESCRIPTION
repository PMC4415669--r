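Package: ecg2id
Title: Two-Lead ECG Human Identification with Sparse Co-Occurrence Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biometric human identification from two simultaneously recorded
    electrocardiogram (ECG) leads. The two leads are fused into a binary
    co-occurrence matrix of paired sample values, reduced by block binarization
    (binary max-pooling) and stored as a sparse coordinate-format fingerprint;
    probes are matched to enrolled templates by Pearson correlation with
    per-subject thresholds trained from enrollment data. Includes reduced
    binary pattern (RBP), basic two-dimensional difference, and PCA lead-fusion
    comparison methods, a false-acceptance/false-rejection evaluation harness
    with threshold sweeps and per-template analysis, readers for WFDB-style and
    CSV two-lead records, and a reproducible synthetic two-lead ECG cohort
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
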