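Package: icpca
Title: Iterative Constrained Principal Component Analysis for
    Symptom-Cognition Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constrained principal component analysis (CPCA) links a block of
    criterion variables (e.g., cognitive test scores) to a block of predictor
    variables (e.g., ordinal symptom ratings) by extracting components from
    the criterion variance that is predictable from the predictors. The
    iterative extension (iCPCA) assesses the reliability of predictor
    loadings through repeated split-half replication, summarised as the
    predictor loading reliability proportion (PLRP), with permutation-based
    significance and Benjamini-Hochberg false discovery rate control.
    Includes Horn's parallel analysis for component retention, a synthetic
    data generator emulating a PANSS-by-MCCB study design, and closed-form
    inference from published group summary statistics (one-way ANOVA,
    Scheffe post hoc contrasts, chi-square independence, two-sample t,
    Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
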