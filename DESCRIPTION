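Package: metabotrans
Title: Translational Metabotyping of LPL-Mediated Hypertriglyceridemia Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and translating metabolomic discriminant models of
    early lipoprotein-lipase (LPL) mediated hypertriglyceridemia risk. Implements
    QC-block and probabilistic quotient normalization of feature tables, per-metabolite
    Mann-Whitney screening with Benjamini-Hochberg correction and fold changes, NIPALS
    PCA and OPLS-DA with cross-validated Q2Y, permutation diagnostics and VIP scores,
    signature selection, projection of a preclinically trained model onto a human
    cohort, and evaluation against clinical triglyceride guidelines. Seeded synthetic
    cohort generators emulate the preclinical, urine and human study designs so the
    whole pipeline is testable without access to the original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
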