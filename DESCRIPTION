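Package: metabopanel
Title: Biomarker Panel Discovery for Untargeted LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible discovery-to-validation workflow for untargeted
    LC-MS metabolomics biomarker studies. Implements feature-table
    preprocessing (80 percent missingness rule, QC coefficient-of-variation
    filtering, half-minimum imputation, median normalization, log2
    transform), OPLS-DA with cross-validated Q2 and a permutation test for
    overfitting (pQ2), VIP scores, Wilcoxon/Benjamini-Hochberg differential
    feature selection, exhaustive radial-kernel SVM panel search with
    cross-validated AUC, ROC analysis with Youden cutoff transfer from a
    discovery to a validation cohort, precursor ppm annotation against a
    reference compound list, and a fully seeded synthetic cohort generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
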