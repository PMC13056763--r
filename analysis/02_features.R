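#!/usr/bin/env Rscript
# Stage 2 — derive per-session features from the raw tables.
#
# Reads the cohort tables written by 01_simulate.R, validates them, and
# derives for each (participant, session): the 24-h reference window's
# volume, container count and volume-weighted USG, plus thirst percentage,
# long-void flag and body-mass change. Writes results/features.csv.

suppressMessages(library(hydrassess))

voids <- read_voids("results/cohort/voids.csv")
assessments <- read_assessments("results/cohort/assessments.csv")
bodymass <- read_bodymass("results/cohort/bodymass.csv")

for (nm in c("voids", "assessments", "bodymass")) {
  viol <- attr(get(nm), "violations")
  if (!is.null(viol) && nrow(viol)) {
    cat(sprintf("%s: %d schema violation(s) excluded\n", nm, nrow(viol)))
  }
}

features <- build_features(voids, assessments, bodymass)
readr::write_csv(features, "results/features.csv", progress = FALSE)

cat(sprintf("derived %d feature rows\n", nrow(features)))
cat(sprintf("24-h USG (weighted): median %.3f | 24-h volume: median %.0f mL | voids: median %d\n",
            median(features$usg_24h), median(features$volume_24h),
            median(features$measured_void_count_24h)))
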