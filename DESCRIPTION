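Package: tscmr
Title: Two-Step cis-Mendelian Randomization with Biasing-Pathway Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Adjusts variant-outcome GWAS summary associations for biasing
    pathways acting through correlated or pleiotropic confounder phenotypes
    (confounding by linkage disequilibrium), the core problem of cis-Mendelian
    randomization for drug-target validation. The crude variant-outcome
    association is decomposed into a path through the exposure and a path
    through the confounder; the confounder path, the product of the
    variant-confounder association and an MR estimate of the confounder-outcome
    effect, is subtracted, and the uncertainty of the adjusted association is
    propagated exactly (delta-method variance of a product of independent
    normals) or by parametric bootstrap. Includes GWAS summary-statistic
    reading and allele harmonization, instrument selection, the standard
    two-sample MR estimator suite (Wald ratio, inverse-variance weighted,
    MR-Egger, weighted median, weighted mode) with Cochran's Q and F-statistic
    diagnostics, an end-to-end pipeline, and a seeded ADEMP-style Monte Carlo
    simulation study of the method's bias and precision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
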