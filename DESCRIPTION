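Package: gaitxai
Title: Explainable Two-Stage Analysis of Parkinsonian Gait from Vertical
    Ground Reaction Force Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Subject-wise validated classification of Parkinson's disease
    from windowed vertical ground reaction force (VGRF) recordings,
    stability-based consensus gait-biomarker selection with Integrated
    Gradients attribution and nonparametric data-level validation
    (Mann-Whitney U, Cliff's delta, Benjamini-Hochberg FDR), and
    continuous Hoehn & Yahr severity regression with gradient boosting
    and noncentral-F post hoc power analysis. Includes a synthetic gait
    cohort generator with ground-truth effect parameters so the full
    pipeline is testable without clinical data, and a small reverse-mode
    automatic differentiation core that powers the three sequence
    backbones (TCN, BiGRU with attention, FCNN-Transformer).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
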