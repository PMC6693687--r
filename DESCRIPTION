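Package: ctdoserisk
Title: Comparing CT Dosimetry Software Outputs and Projecting Lifetime
    Cancer Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing organ equivalent doses produced by two CT
    dosimetry programs built on different computational phantoms (a
    hermaphrodite mathematical phantom versus sex-specific voxelised
    reference phantoms) and for projecting the downstream consequences for
    cancer-incidence estimates.  Implements reference-denominated
    Bland-Altman agreement analysis, Passing-Bablok regression with
    rank-based confidence intervals, a CUSUM linearity test with a
    log-transform fallback, and projection of median organ doses into
    lifetime attributable risk (LAR) of cancer incidence per 100,000
    persons across exposure ages 18-80 using linearly interpolated BEIR VII
    risk coefficients.  Includes a synthetic paired-dose study generator so
    the full pipeline is testable without access to the original scan
    records.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
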