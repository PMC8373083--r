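Package: poolcs
Title: Compressed-Sensing Recovery of Single-Cell Expression Profiles from Overlapped Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of overlapped cell-to-pool assignment matrices for
    plate-based single-cell RNA-seq, simulation of pooled expression
    measurements (including multiplicative "turbulence" noise and TPM
    depth-sharing normalization), and reconstruction of per-cell expression
    profiles from pooled measurements by basis pursuit (l1) or ridge (l2)
    regularization, gene by gene, with a block-parallel scheme for large cell
    numbers. Includes a zero-inflated synthetic expression-profile generator
    with cell-type block structure, Pearson-correlation and gene-detection
    evaluation metrics, library-cost accounting, lossless TSV/CSV/Matrix
    Market I/O, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    withr,
    optparse,
    parallel,
    stats,
    tools,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
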