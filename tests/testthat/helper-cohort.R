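# shared fixture builders -------------------------------------------------

t0 <- as.POSIXct("2024-05-06 08:00:00", tz = "UTC")

# a void table at given stream hours (h after collection start)
mk_voids <- function(hours, volume = 200, usg = 1.012, pid = "P001") {
  tibble::tibble(
    participant_id = pid,
    time = t0 + hours * 3600,
    volume_ml = rep_len(volume, length(hours)),
    usg = rep_len(usg, length(hours))
  )
}

# one complete assessment record at the scoring boundary
mk_record <- function(sex = "male", intake = 3697, count = 7,
                      spot = 250, color = 2) {
  list(sex = sex, reported_intake_24h = intake,
       reported_void_count_24h = count, spot_volume = spot,
       color_score = color)
}

# exhaustive pair-counting AUC oracle (concordant + half ties)
auc_pairs <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# trapezoidal area under the empirical ROC curve
auc_trapezoid <- function(scores, labels, positive) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- labels == positive
  tpr <- c(0, vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)))
  fpr <- c(0, vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# match truth rows to assessment rows
truth_for <- function(cohort, assessments = cohort$assessments) {
  m <- match(paste(assessments$participant_id, assessments$session),
             paste(cohort$truth$participant_id, cohort$truth$session))
  cohort$truth[m, , drop = FALSE]
}
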