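Package: densvar
Title: Effect of Reader Label Variability on Mammographic Density Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how inter-reader
    variability in visual-analogue-scale (VAS) breast-density labels affects
    learned density models. Provides a synthetic mammogram-like cohort
    generator with a three-component reader-variability model (systematic
    image-dependent bias, monotone distribution warps, random error), the
    standard preprocessing chain, a closed-form ridge mapping over extracted
    image features with subject-level cross-validation, a small end-to-end
    convolutional model trained with a masked multi-output loss for missing
    reader labels, linear-probe comparison of learned representations, and
    evaluation utilities (Spearman rank correlation, RMSE, percentile
    bootstrap intervals, reader-level aggregates, case-control quintile odds
    ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    stats,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
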