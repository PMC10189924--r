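Package: sitebias
Title: Acquisition-Site Bias Audits for Histopathology Image Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify acquisition-site (hospital)
    signatures in patch-level feature embeddings of hematoxylin-and-eosin
    whole-slide images. Provides a synthetic multi-site cohort generator
    with a tunable site-effect knob (stain-matrix shifts plus band-limited
    noise textures), mosaic patch sampling by RGB-histogram clustering,
    a pluggable patch feature extractor with a deterministic handcrafted
    baseline, a patient-aware repeated-split site-classification probe,
    median-of-min slide retrieval, and an observed-versus-expected
    same-site retrieval audit with a permutation null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
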