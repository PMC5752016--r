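Package: crmscan
Title: Expression-Coupled Screening of Cis-Regulatory Elements and Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens user-supplied cis-regulatory elements (CREs) and pairwise
    CRE modules (CRMs) for association with categorized gene-expression maxima
    in fixed-length promoter sets. Candidate calls are made against a
    randomized-motif background (per-category standard deviations of the
    distributions of expression maxima of random motifs, majority-voted over
    many background replicates). For candidate CRE pairs three positional
    features are computed: an exact binomial test of member order relative to
    the transcription start site, a Kolmogorov-Smirnov test of member spacing
    against a stochastic null, and Bowley's quartile skewness of module
    positions. An evolutionarily trained two-class feedforward network
    ensemble groups candidate pairs by these features. Includes a synthetic
    promoter/catalog generator with planted signals for calibration and
    benchmarking, and file-based run drivers with a thin command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    BiocGenerics,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
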