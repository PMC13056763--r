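#' Cut-offs of the four-item hydration self-assessment score
#'
#' Each marker is scored 0 when it meets its "low urine concentration"
#' criterion and 1 otherwise. All thresholds are inclusive on the
#' low-concentration side:
#' fluid intake >= 2697 mL (female) / >= 3697 mL (male); spot void volume
#' >= 250 mL; 24-h void frequency >= 7; urine color shade <= 2.
#'
#' @param intake_female_ml,intake_male_ml,spot_volume_ml,void_frequency,color_max_low
#'   Override individual thresholds for sensitivity analyses.
#' @return A list of class `item_cutoffs`.
#' @export
item_cutoffs <- function(intake_female_ml = 2697,
                         intake_male_ml = 3697,
                         spot_volume_ml = 250,
                         void_frequency = 7,
                         color_max_low = 2) {
  stopifnot(intake_female_ml > 0, intake_male_ml > 0, spot_volume_ml > 0,
            void_frequency > 0, color_max_low %in% 1:6)
  structure(list(intake_female_ml = intake_female_ml,
                 intake_male_ml = intake_male_ml,
                 spot_volume_ml = spot_volume_ml,
                 void_frequency = void_frequency,
                 color_max_low = color_max_low),
            class = "item_cutoffs")
}

#' Score the four self-assessment items
#'
#' Applies the four binary cut-offs to one or more assessment records and
#' returns the item scores, their total (0-4) and the predicted class:
#' a total of 0-1 suggests a low urine concentration (optimal fluid
#' intake), a total of 2-4 a high urine concentration (suboptimal intake).
#'
#' Missing marker values abort scoring — the score is defined only on
#' complete four-item records; use [classify_cohort()] to split a cohort
#' into complete and incomplete records instead.
#'
#' @param rec A list/tibble with fields `sex` ("female"/"male"),
#'   `reported_intake_24h` (mL), `reported_void_count_24h`,
#'   `spot_volume` (mL) and `color_score` (1-7). Vectors are allowed.
#' @param cutoffs An [item_cutoffs()] list.
#' @return A tibble with columns `intake_item`, `frequency_item`,
#'   `volume_item`, `color_item` (each 0/1), `total` and
#'   `predicted_class`.
#' @export
#' @examples
#' score_items(list(sex = "male", reported_intake_24h = 3697,
#'                  reported_void_count_24h = 7, spot_volume = 250,
#'                  color_score = 2))
score_items <- function(rec, cutoffs = item_cutoffs()) {
  need <- c("sex", "reported_intake_24h", "reported_void_count_24h",
            "spot_volume", "color_score")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop("missing marker field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vals <- rec[need]
  if (any(vapply(vals, function(v) any(is.na(v)), logical(1)))) {
    stop("missing marker values; the four-item score is defined only on ",
         "complete records", call. = FALSE)
  }
  if (!all(rec$sex %in% c("female", "male"))) {
    stop("unknown sex value; expected \"female\" or \"male\"", call. = FALSE)
  }
  thr_intake <- ifelse(rec$sex == "female", cutoffs$intake_female_ml,
                       cutoffs$intake_male_ml)
  intake_item <- as.integer(!(rec$reported_intake_24h >= thr_intake))
  frequency_item <- as.integer(
    !(rec$reported_void_count_24h >= cutoffs$void_frequency))
  volume_item <- as.integer(!(rec$spot_volume >= cutoffs$spot_volume_ml))
  color_item <- as.integer(!(rec$color_score <= cutoffs$color_max_low))
  total <- intake_item + frequency_item + volume_item + color_item
  tibble::tibble(
    intake_item = intake_item, frequency_item = frequency_item,
    volume_item = volume_item, color_item = color_item, total = total,
    predicted_class = ifelse(total >= 2, "high_concentration",
                             "low_concentration")
  )
}

#' Reference classification of 24-hour USG
#'
#' Classifies a 24-h USG against one of two reference cut-offs, after
#' rounding to 3 decimals (USG is recorded to 0.001, and exact decimal
#' comparison avoids float misclassification at the boundary):
#' * `"low"`: low concentration iff USG <= 1.012 ("optimal fluid intake"),
#'   high iff >= 1.013 ("suboptimal fluid intake");
#' * `"high"`: high concentration iff USG >= 1.020 (conventional
#'   underhydration threshold).
#'
#' @param usg_24h Numeric vector in \[1.000, 1.040\].
#' @param cutoff `"low"` (1.012) or `"high"` (1.020).
#' @return Character vector, `"low_concentration"` or
#'   `"high_concentration"`.
#' @export
#' @examples
#' reference_label(c(1.012, 1.013), "low")
reference_label <- function(usg_24h, cutoff = c("low", "high")) {
  cutoff <- match.arg(cutoff)
  if (any(is.na(usg_24h)) || any(usg_24h < 1.000) || any(usg_24h > 1.040)) {
    stop("USG out of the physiologic range [1.000, 1.040]", call. = FALSE)
  }
  u <- round(usg_24h, 3)
  if (cutoff == "low") {
    ifelse(u <= 1.012, "low_concentration", "high_concentration")
  } else {
    ifelse(u >= 1.020, "high_concentration", "low_concentration")
  }
}

#' Classify a cohort with the four-item score and a USG reference
#'
#' Joins [score_items()] and [reference_label()] over per-session feature
#' rows. Records with any missing marker (or missing reference USG) are
#' excluded from the main table and returned separately in the
#' `"incomplete"` attribute.
#'
#' @param features Tibble from [build_features()] (or equivalent) with the
#'   four marker columns, `sex`, and a reference USG column.
#' @param cutoffs An [item_cutoffs()] list.
#' @param usg_cutoff `"low"` or `"high"` reference cut-off.
#' @param usg_col Name of the reference USG column (default `usg_24h`).
#' @return Tibble of complete rows with item scores, `total`,
#'   `predicted_class` and `reference`; incomplete rows are in
#'   `attr(, "incomplete")`.
#' @export
classify_cohort <- function(features, cutoffs = item_cutoffs(),
                            usg_cutoff = c("low", "high"),
                            usg_col = "usg_24h") {
  usg_cutoff <- match.arg(usg_cutoff)
  stopifnot(usg_col %in% names(features))
  key <- paste(features$participant_id, features$session, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (participant, session) keys in features table",
         call. = FALSE)
  }
  need <- c("sex", "reported_intake_24h", "reported_void_count_24h",
            "spot_volume", "color_score")
  complete <- stats::complete.cases(features[, c(need, usg_col)])
  kept <- features[complete, , drop = FALSE]
  dropped <- features[!complete, , drop = FALSE]
  scored <- score_items(kept, cutoffs)
  out <- dplyr::bind_cols(
    kept[, c("participant_id", "session", need, usg_col)], scored)
  out$reference <- reference_label(out[[usg_col]], usg_cutoff)
  out <- tibble::as_tibble(out)
  attr(out, "incomplete") <- tibble::as_tibble(dropped)
  attr(out, "usg_cutoff") <- usg_cutoff
  out
}
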