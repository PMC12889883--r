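Package: scaledabund
Title: Internal-Standard Scaled Abundances for Metagenomic Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Corrects for compositionality in metagenomic sequencing (MGS)
    abundance tables using an exogenous internal standard added to every
    sample at a known concentration. Implements the Scaled Abundance metric
    (the ratio of a taxon's relative abundance to that of the internal
    standard, multiplied by the standard's known actual abundance), taxon
    bias-ratio estimation with confidence intervals, absolute-abundance
    back-calculation, and pairwise fold-change analysis. Includes the
    evaluation procedures used to assess the metric (replicate and
    between-sample coefficients of variation, through-origin proportionality
    regressions with CV goodness-of-fit, internal-standard rotation, and
    limit-of-quantitation profiling) and a generative simulator of the
    biased-multinomial MGS measurement model with scenario builders for mock
    communities, spike-in experiments across diverse backgrounds, and
    dilution series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
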