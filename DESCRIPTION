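Package: snoRoR
Title: Dual-Channel Saturation-Fluorescence Quantification of Protein
    Abundance and Cysteine S-Nitrosylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies changes in protein abundance and cysteine
    S-nitrosylation (S-NO) from two-dimensional gel electrophoresis
    spot-volume tables produced by paired ascorbate-treated (Asc+) and
    neocuproine-stabilized (Asc-) sample fractions labeled with a
    thiol-saturating fluorescent maleimide dye.  Implements reference-gel
    selection and per-gel bias-factor normalization, the signed fold
    convention, the ratio-of-ratios (RoR) statistic that normalizes the
    S-NO signal for protein abundance, spot-wise Welch tests with
    Benjamini-Hochberg correction and fold/p selection, Venn
    classification of differential spots, and a from-scratch multivariate
    adaptive regression splines (MARS) classifier with 10-fold
    cross-validation, 80/20 split validation, variable importance, and
    ROC/AUC assessment.  A synthetic gel-set generator with known ground
    truth and a packaged spot-profile reference table support end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
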