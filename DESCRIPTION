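Package: hydrassess
Title: A Four-Item Hydration Self-Assessment Model and Its Diagnostic
    Evaluation Chain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements a four-item hydration self-assessment score
    (self-reported fluid intake, urine void frequency, spot urine volume,
    and urine color) for classifying low versus high 24-hour urine
    concentration, together with the full evaluation chain: overlapping
    24-hour windowing of a 32-hour void stream, volume-weighted 24-hour
    urine specific gravity, reference classification at two USG cut-offs
    (1.012 and 1.020), diagnostic-accuracy statistics (contingency tables,
    rank-based AUC, rank-biserial correlation, Cramer's V, Spearman
    correlation, rank and exact tests), stepwise logistic variable
    selection, and a synthetic-cohort generator with configurable coupling
    between latent urine concentration and the observable markers so that
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
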