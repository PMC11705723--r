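Package: aafscreen
Title: Drug Sensitivity and Combination Synergy Analysis for
    Ascites-Conditioned Viability Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput viability screens of
    ovarian cancer cell lines cultured with patient-derived acellular
    ascites fluid (AAF). Provides plate quality control (Z-prime),
    control- and vehicle-based normalization of raw luminescence,
    four-parameter log-logistic dose-response fitting with outlier
    removal, drug sensitivity scores (DSS, normalized area under the
    inhibition curve), combination scoring via the Combination Ratio,
    zero-interaction-potency (ZIP) synergy deltas and 100-VUS response
    surface scores, treatment ranking, and the downstream statistical
    layer (two-way ANOVA with Tukey post-hoc tests, Holm-corrected
    Pearson correlation matrices, Ward-D2 hierarchical clustering,
    IgG-normalized phospho-marker fold changes). A synthetic-screen
    generator with known ground truth emulates the study design so
    every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    car,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
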