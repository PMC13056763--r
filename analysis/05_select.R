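#!/usr/bin/env Rscript
# Stage 5 — stepwise variable selection on the cohort.
#
# Re-runs the exploratory model-building procedure on the synthetic
# cohort: candidate markers are the four item scores plus thirst, vitals
# and the long-void/body-mass flags; demographics are adjustment
# covariates. Forward entry at p <= 0.10, backward retention at p < 0.05.
# Writes results/selection.json.

suppressMessages({library(hydrassess); library(dplyr)})

features <- readr::read_csv("results/features.csv", show_col_types = FALSE)
participants <- readr::read_csv("results/cohort/participants.csv",
                                show_col_types = FALSE)

cl <- classify_cohort(features, usg_cutoff = "low")
dat <- cl |>
  left_join(select(features, "participant_id", "session", "thirst_pct",
                   "long_void", "mass_loss_flag", "systolic_bp",
                   "heart_rate"),
            by = c("participant_id", "session")) |>
  left_join(select(participants, "participant_id", "age", "bmi",
                   "supplement_use", "alcohol_use", "nicotine_use"),
            by = "participant_id")

y <- as.integer(dat$reference == "high_concentration")
sel <- stepwise_select(
  dat, y,
  candidates = c("intake_item", "frequency_item", "volume_item",
                 "color_item", "thirst_pct", "long_void", "mass_loss_flag",
                 "systolic_bp", "heart_rate"),
  covariates = c("age", "sex", "bmi", "supplement_use", "alcohol_use",
                 "nicotine_use"))

cat("entered during forward steps:", paste(sel$entered, collapse = ", "), "\n")
cat("retained in the final model:", paste(sel$retained, collapse = ", "), "\n")
cat(sprintf("final-model AUC: %.3f\n", sel$model_auc))
print(as.data.frame(sel$coefficients), digits = 3)

jsonlite::write_json(
  list(retained = sel$retained, entered = sel$entered,
       model_auc = sel$model_auc,
       coefficients = sel$coefficients,
       dropped_constant = sel$dropped_constant),
  "results/selection.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/selection.json\n")
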