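Package: tdcrawl
Title: Rank-Dependent, Motif-Free Alignment of k-mer Level Binding Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements Top-Down Crawl, a greedy rank-dependent algorithm for
    aligning fixed-length k-mers carrying quantitative binding measurements
    (SELEX-seq relative enrichment, protein binding microarray scores, and
    similar assays), together with enrichment-weighted position weight matrix
    (PWM) construction, PWM-based k-mer shift assignment for cross-method
    comparison, pentamer-based DNA shape features (minor groove width and
    electrostatic potential), and an elastic-net regression harness that
    scores alignment quality by cross-validated R-squared. A synthetic
    SELEX-like generator with known ground-truth offsets supports end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
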