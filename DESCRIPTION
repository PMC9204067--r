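Package: museclock
Title: Murine Epigenetic Clocks from DNA Methylation Beta Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, applies, and validates epigenetic clocks for mice from
    Infinium-style DNA methylation beta-value matrices. Implements slope-based
    selection of age-associated CpGs on within-strain normalized age scales,
    cross-strain intersection of candidate sites, a single-CpG ensemble age
    predictor, an exhaustive 4-CpG multivariate pyrosequencing clock
    (including the published C57BL/6 coefficients), strain methylome
    comparison with exact rank-sum differential methylation, and mapping of
    mouse candidate CpGs to homologous human array CpGs with correlation
    t-tests. A synthetic cohort generator reproduces the statistical
    structure of the study design so the full pipeline can be exercised
    without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
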