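Package: mrpipe
Title: Two-Sample Mendelian Randomization with Mediation and PheWAS Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization on GWAS summary
    statistics: instrument selection with LD clumping and instrument-strength
    filtering, allele-specific harmonization of exposure and outcome effects,
    inverse-variance-weighted, MR-Egger, weighted-median and weighted-mode
    causal estimators, Cochran's Q heterogeneity, leave-one-out and MR-PRESSO
    sensitivity analysis, two-step mediation with product-of-coefficients
    indirect effects and delta-method standard errors, and matched-control
    PheWAS trait enrichment by Fisher's exact test. A synthetic
    summary-statistics generator with known ground truth supports calibration
    and power checks of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
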