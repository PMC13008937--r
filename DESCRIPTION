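Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation for
    Proteome-Wide Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) screens of many
    exposures against a rare binary outcome, and for two-step MR mediation
    through an intermediate trait. Reads GWAS summary statistics (generic and
    FinnGen-style column dialects, optionally gzip-compressed), selects and
    clumps instruments, harmonizes exposure and outcome effect alleles, and
    fits five causal estimators (inverse-variance weighted, MR-Egger, weighted
    median, simple mode, weighted mode) with Cochran heterogeneity, odds-ratio
    reporting, leave-one-out sensitivity analysis, reverse-MR screening and a
    direction-consistency filter. Mediated, direct and total effects are
    decomposed by the product-of-coefficients method with a delta-method
    standard error. A seeded synthetic GWAS generator draws exposure, mediator
    and outcome summary statistics under a known causal diagram, with an
    individual-level simulator as an independent oracle, so the whole pipeline
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
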