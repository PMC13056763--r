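#!/usr/bin/env Rscript
# Stage 3 — apply the four-item score and both USG reference labels.
#
# Scores every complete feature row with the four binary cut-offs
# (intake >= 2697/3697 mL by sex, spot volume >= 250 mL, frequency >= 7,
# color <= 2) and labels each row against the low (<= 1.012) and high
# (>= 1.020) USG cut-offs. Writes results/classified_low.csv and
# results/classified_high.csv.

suppressMessages(library(hydrassess))

features <- readr::read_csv("results/features.csv", show_col_types = FALSE)

for (cutoff in c("low", "high")) {
  cl <- classify_cohort(features, usg_cutoff = cutoff)
  readr::write_csv(cl, sprintf("results/classified_%s.csv", cutoff),
                   progress = FALSE)
  inc <- attr(cl, "incomplete")
  cat(sprintf("cut-off %s: %d complete rows (%d incomplete excluded)\n",
              cutoff, nrow(cl), nrow(inc)))
  print(table(score = cl$total, reference = cl$reference))
}
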