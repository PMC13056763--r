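#!/usr/bin/env Rscript
# Stage 4 — diagnostic evaluation of the model and its items.
#
# For each session and USG cut-off: rank AUC of the graded 0-4 score,
# per-item AUCs, and sensitivity/specificity/accuracy with TP/TN/FP/FN
# counts. Writes results/evaluation.csv and prints the tables next to the
# published counts for the same layout.

suppressMessages({library(hydrassess); library(dplyr)})

features <- readr::read_csv("results/features.csv", show_col_types = FALSE)

rows <- list()
for (cutoff in c("low", "high")) {
  for (sess in c("morning", "afternoon")) {
    cl <- classify_cohort(features[features$session == sess, ],
                          usg_cutoff = cutoff)
    rep <- evaluate_model(cl)
    rep$session <- sess
    rep$usg_cutoff <- cutoff
    rows[[paste(cutoff, sess)]] <- rep
  }
}
evaluation <- bind_rows(rows) |>
  select("session", "usg_cutoff", dplyr::everything())
readr::write_csv(evaluation, "results/evaluation.csv", progress = FALSE)

cat("synthetic-cohort evaluation (results/evaluation.csv):\n")
print(as.data.frame(evaluation), digits = 3)

cat("\npublished counts for the same layout (validation_counts()):\n")
print(as.data.frame(validation_counts()), digits = 3)
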