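#' Read a cohort void table from delimited text
#'
#' Expects columns `participant_id`, `time` (ISO-8601), `volume_ml`,
#' `usg`. Rows violating the schema (non-positive volume, USG outside
#' \[1.000, 1.040\], unparsable timestamp) are collected — with their line
#' numbers — into the `"violations"` attribute and excluded; a missing
#' required column is fatal.
#'
#' @param path Path to a CSV file.
#' @return Tibble of valid void records, violations in
#'   `attr(, "violations")`.
#' @export
read_voids <- function(path) {
  raw <- read_checked(path, c("participant_id", "time", "volume_ml", "usg"))
  raw$time <- parse_iso_time(raw$time)
  bad <- is.na(raw$time) | is.na(raw$volume_ml) | raw$volume_ml <= 0 |
    is.na(raw$usg) | raw$usg < 1.000 | raw$usg > 1.040
  keep_violations(raw, bad,
                  "non-positive volume, out-of-range USG or bad timestamp")
}

#' Read a cohort assessment table
#'
#' Required columns: `participant_id`, `session`, `sex`,
#' `reported_intake_24h`, `reported_void_count_24h`, `spot_volume`,
#' `color_score`. Rows with a session outside
#' \{morning, afternoon\} or a color outside 1..7 are collected as
#' violations.
#'
#' @inheritParams read_voids
#' @return Tibble of valid assessment records.
#' @export
read_assessments <- function(path) {
  raw <- read_checked(path, c("participant_id", "session", "sex",
                              "reported_intake_24h",
                              "reported_void_count_24h", "spot_volume",
                              "color_score"))
  if ("assess_time" %in% names(raw) && !inherits(raw$assess_time, "POSIXct")) {
    raw$assess_time <- parse_iso_time(raw$assess_time)
  }
  bad <- !raw$session %in% c("morning", "afternoon") |
    !raw$color_score %in% 1:7
  keep_violations(raw, bad, "bad session label or color score")
}

#' Read a body-mass series table
#'
#' Required columns: `participant_id`, `day1_kg`, `day2_kg`, `day3_kg`;
#' non-positive masses are violations.
#'
#' @inheritParams read_voids
#' @return Tibble of valid body-mass records.
#' @export
read_bodymass <- function(path) {
  raw <- read_checked(path, c("participant_id", "day1_kg", "day2_kg",
                              "day3_kg"))
  bad <- raw$day1_kg <= 0 | raw$day2_kg <= 0 | raw$day3_kg <= 0 |
    is.na(raw$day1_kg) | is.na(raw$day2_kg) | is.na(raw$day3_kg)
  keep_violations(raw, bad, "non-positive body mass")
}

# lenient ISO-8601 parser: unparsable entries become NA (collected as
# schema violations) instead of aborting the read
parse_iso_time <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- as.POSIXct(strptime(x[miss], "%Y-%m-%d %H:%M:%S",
                                     tz = "UTC"))
  }
  out
}

read_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  raw
}

keep_violations <- function(raw, bad, reason) {
  bad[is.na(bad)] <- TRUE
  out <- tibble::as_tibble(raw[!bad, , drop = FALSE])
  viol <- tibble::as_tibble(raw[bad, , drop = FALSE])
  viol$line <- which(bad) + 1L  # header is line 1
  viol$reason <- reason
  attr(out, "violations") <- viol
  out
}

#' Write a synthetic cohort as delimited text tables
#'
#' Writes `voids.csv`, `diaries.csv`, `assessments.csv`, `bodymass.csv`,
#' `participants.csv` and `truth.csv` with fixed column layouts and
#' ISO-8601 timestamps (timezone-naive local clock).
#'
#' @param cohort A `hyd_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hyd_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%S")
  tabs <- list(
    voids = dplyr::mutate(cohort$voids, time = fmt_time(.data$time)),
    diaries = cohort$diaries,
    assessments = dplyr::mutate(cohort$assessments,
                                assess_time = fmt_time(.data$assess_time)),
    bodymass = cohort$bodymass,
    participants = cohort$participants,
    truth = cohort$truth
  )
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tabs[[nm]], p, progress = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Published classification counts for the four-item model
#'
#' The TP/TN/FP/FN counts, AUCs and printed sensitivity/specificity of the
#' four-item model and its individual items, for morning and afternoon
#' assessments at both USG reference cut-offs, as reported in the model's
#' human validation study. Used as the fixed arithmetic fixture for the
#' diagnostics layer (the counts are inputs; all rates are recomputed).
#'
#' @return A tibble with columns `session`, `usg_cutoff`, `variable`,
#'   `auc`, `sensitivity_pct`, `specificity_pct`, `tp`, `tn`, `fp`, `fn`.
#' @export
validation_counts <- function() {
  path <- system.file("extdata", "model_validation_counts.csv",
                      package = "hydrassess", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run the full evaluation pipeline on a synthetic cohort
#'
#' simulate -> features -> score -> evaluate -> select, as one
#' reproducible unit. All randomness derives from `config$seed`; when
#' `out_dir` is given, every stage's table is written along with a run log
#' carrying the seed and a configuration hash, so an archived run can be
#' reproduced exactly.
#'
#' @param config A [generator_config()].
#' @param usg_cutoff `"low"` or `"high"` reference cut-off.
#' @param positive Positive class passed to [evaluate_model()] (default:
#'   cut-off-specific convention).
#' @param out_dir Optional output directory.
#' @param select Run the stepwise-selection stage (default TRUE).
#' @return List of class `hyd_run` with `cohort`, `features`,
#'   `classified`, `report`, `selection`, `log`.
#' @export
run_pipeline <- function(config = generator_config(),
                         usg_cutoff = c("low", "high"),
                         positive = NULL, out_dir = NULL, select = TRUE) {
  usg_cutoff <- match.arg(usg_cutoff)
  cohort <- generate_cohort(config)
  feats <- build_features(cohort$voids, cohort$assessments, cohort$bodymass)
  classified <- classify_cohort(feats, usg_cutoff = usg_cutoff)
  report <- evaluate_model(classified, positive = positive)

  selection <- NULL
  if (select) {
    sel_data <- dplyr::left_join(
      classified,
      dplyr::select(feats, "participant_id", "session",
                    dplyr::any_of(c("thirst_pct", "thirst_distress_mm",
                                    "long_void", "mass_loss_flag",
                                    "systolic_bp", "diastolic_bp",
                                    "heart_rate"))),
      by = c("participant_id", "session"))
    sel_data <- dplyr::left_join(
      sel_data,
      dplyr::select(cohort$participants, "participant_id", "age", "bmi",
                    "supplement_use", "medicine_use", "alcohol_use",
                    "nicotine_use"),
      by = "participant_id")
    cand <- intersect(c("intake_item", "frequency_item", "volume_item",
                        "color_item", "thirst_pct", "long_void",
                        "mass_loss_flag", "systolic_bp", "heart_rate"),
                      names(sel_data))
    covs <- intersect(c("age", "sex", "bmi", "supplement_use",
                        "medicine_use", "alcohol_use", "nicotine_use"),
                      names(sel_data))
    y <- as.integer(sel_data$reference == "high_concentration")
    selection <- stepwise_select(sel_data, y, candidates = cand,
                                 covariates = covs)
  }

  log <- list(
    seed = config$seed,
    usg_cutoff = usg_cutoff,
    positive = attr(report, "positive"),
    n_participants = config$n_participants,
    n_complete = nrow(classified),
    n_incomplete = nrow(attr(classified, "incomplete")),
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("hydrassess"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    readr::write_csv(feats, file.path(out_dir, "features.csv"),
                     progress = FALSE)
    readr::write_csv(classified, file.path(out_dir, "classified.csv"),
                     progress = FALSE)
    readr::write_csv(report, file.path(out_dir, "report.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      c(log, list(report = report,
                  selection_retained = selection$retained %||% character())),
      file.path(out_dir, "run.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(cohort = cohort, features = feats, classified = classified,
                 report = report, selection = selection, log = log),
            class = "hyd_run")
}

#' @export
print.hyd_run <- function(x, ...) {
  cat(sprintf("<hyd_run> cut-off %s, %d complete records, seed %d\n",
              x$log$usg_cutoff, x$log$n_complete, x$log$seed))
  print(x$report)
  invisible(x)
}
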