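#' Extract the two overlapping 24-hour collection windows
#'
#' A 32-h void stream, assessed in the morning and again 8 h later, yields
#' two 24-h reference windows: `(t - 24 h, t]` for each assessment time `t`.
#' Membership is half-open — a void produced at the assessment moment
#' belongs to the period it concludes — so with the default 8-h session
#' offset the windows share exactly 16 h and a void may belong to both.
#'
#' @param voids Tibble of one participant's voids with columns `time`
#'   (POSIXct), `volume_ml` (> 0) and `usg`.
#' @param assessment_times Length-2 POSIXct vector (morning, afternoon).
#' @return A list of two `collection_window` objects labelled
#'   `morning` and `afternoon`. Each carries the member voids, the
#'   half-open interval, and `partial = TRUE` when the stream starts less
#'   than 24 h before the assessment (incomplete coverage).
#' @export
extract_windows <- function(voids, assessment_times) {
  if (is.null(voids) || nrow(voids) == 0) {
    stop("cannot extract windows from an empty void list", call. = FALSE)
  }
  stopifnot(length(assessment_times) == 2)
  if (any(voids$volume_ml <= 0)) {
    stop("void volumes must be strictly positive", call. = FALSE)
  }
  voids <- voids[order(voids$time), , drop = FALSE]
  labels <- c("morning", "afternoon")
  out <- lapply(seq_along(labels), function(i) {
    t_end <- assessment_times[i]
    t_start <- t_end - 24 * 3600
    # flag (not an error) when the stream cannot cover a full 24 h:
    # the assessment falls earlier than 24 h after the first recorded void
    partial <- as.numeric(difftime(t_end, min(voids$time),
                                   units = "hours")) < 24 - 1e-9
    member <- voids$time > t_start & voids$time <= t_end
    structure(
      list(participant_id = voids$participant_id[1] %||% NA_character_,
           start = t_start, end = t_end, label = labels[i],
           voids = voids[member, , drop = FALSE], partial = partial),
      class = "collection_window"
    )
  })
  names(out) <- labels
  out
}

#' @export
print.collection_window <- function(x, ...) {
  cat(sprintf("<collection_window %s> (%s, %s], %d voids%s\n",
              x$label, format(x$start), format(x$end), nrow(x$voids),
              if (x$partial) " [partial coverage]" else ""))
  invisible(x)
}

as_window_voids <- function(window) {
  if (inherits(window, "collection_window")) window$voids else window
}

#' Volume-weighted 24-hour urine specific gravity
#'
#' The 24-h USG of a collection window is the volume-weighted mean of its
#' member voids, `sum(usg_i * vol_i) / sum(vol_i)`, which always lies
#' between the smallest and largest member USG.
#'
#' @param window A `collection_window` or a tibble with columns `usg` and
#'   `volume_ml`.
#' @return The weighted-mean specific gravity.
#' @export
#' @examples
#' weighted_usg(tibble::tibble(usg = c(1.010, 1.020),
#'                             volume_ml = c(1000, 1000)))
weighted_usg <- function(window) {
  v <- as_window_voids(window)
  if (is.null(v) || nrow(v) == 0) {
    stop("cannot compute weighted USG of an empty window", call. = FALSE)
  }
  if (any(v$volume_ml <= 0)) {
    stop("void volumes must be strictly positive", call. = FALSE)
  }
  total <- sum(v$volume_ml)
  if (total <= 0) stop("zero total volume in window", call. = FALSE)
  sum(v$usg * v$volume_ml) / total
}

#' Summary metrics of a collection window
#'
#' @inheritParams weighted_usg
#' @return A list with `volume_24h` (mL), `void_count_24h` and
#'   `weighted_usg`.
#' @export
window_metrics <- function(window) {
  v <- as_window_voids(window)
  if (is.null(v) || nrow(v) == 0) {
    stop("cannot summarise an empty window", call. = FALSE)
  }
  list(volume_24h = sum(v$volume_ml),
       void_count_24h = nrow(v),
       weighted_usg = weighted_usg(v))
}

#' Thirst visual-analogue score as a percentage
#'
#' Converts a mark on the 175-mm thirst VAS to a percentage of the full
#' scale (`100 * mm / 175`) and classifies "not thirsty" as a score at or
#' below 40% (boundary inclusive). The 125-mm "extremely" anchor is part of
#' the instrument's layout but does not enter the calculation.
#'
#' @param vas_mm Non-negative mark position in mm.
#' @return A list with `percent` and logical `not_thirsty`.
#' @export
#' @examples
#' thirst_percent(70) # 40%, still classified not thirsty
thirst_percent <- function(vas_mm) {
  if (any(is.na(vas_mm)) || any(vas_mm < 0)) {
    stop("VAS marks must be non-negative", call. = FALSE)
  }
  pct <- 100 * vas_mm / 175
  list(percent = pct, not_thirsty = pct <= 40)
}

#' Body-mass change from a two-day baseline
#'
#' Baseline is the average of the Day 1 and Day 3 fasted morning masses;
#' the percent change of the Day 2 mass from that baseline is flagged when
#' it is a decrease of at least 1% (boundary inclusive). Gains never flag.
#'
#' @param day1_kg,day2_kg,day3_kg Positive fasted morning body masses (kg).
#' @return A list with `percent_change` and logical `flag_ge_1pct`.
#' @export
#' @examples
#' body_mass_change(80, 79.2, 80)
body_mass_change <- function(day1_kg, day2_kg, day3_kg) {
  if (any(c(day1_kg, day2_kg, day3_kg) <= 0, na.rm = FALSE) ||
      any(is.na(c(day1_kg, day2_kg, day3_kg)))) {
    stop("body masses must be positive", call. = FALSE)
  }
  baseline <- (day1_kg + day3_kg) / 2
  pct <- 100 * (day2_kg - baseline) / baseline
  # small tolerance so a loss of exactly 1% (at scale precision) flags
  list(percent_change = pct, flag_ge_1pct = pct <= -1 + 1e-9)
}

#' Long-void flag from void duration
#'
#' A spot-void duration of at least 16 s indicates a larger urine volume.
#'
#' @param duration_s Non-negative duration in seconds.
#' @return Logical vector.
#' @export
long_void_flag <- function(duration_s) {
  if (any(is.na(duration_s)) || any(duration_s < 0)) {
    stop("void durations must be non-negative", call. = FALSE)
  }
  duration_s >= 16
}

#' Derive per-session features for a whole cohort
#'
#' Joins each participant-session's self-assessment responses with the
#' measured properties of its 24-h reference window (volume, container
#' count, volume-weighted USG) and the derived candidate markers (thirst
#' percentage, long-void flag, body-mass change when available).
#'
#' @param voids Cohort void table (`participant_id`, `time`, `volume_ml`,
#'   `usg`).
#' @param assessments Cohort assessment table; must carry `participant_id`,
#'   `session`, `assess_time` and the four self-assessed markers.
#' @param bodymass Optional body-mass series table with columns
#'   `participant_id`, `day1_kg`, `day2_kg`, `day3_kg`.
#' @return A tibble with one row per complete (participant, session):
#'   measured `volume_24h`, `void_count_24h`, `usg_24h` plus the
#'   self-reported markers and derived flags.
#' @export
build_features <- function(voids, assessments, bodymass = NULL) {
  stopifnot(all(c("participant_id", "session", "assess_time") %in%
                  names(assessments)))
  split_voids <- split(voids, voids$participant_id)
  per_row <- function(pid, t_end) {
    pv <- split_voids[[pid]]
    if (is.null(pv) || nrow(pv) == 0) {
      return(list(volume_24h = NA_real_, void_count_24h = NA_integer_,
                  usg_24h = NA_real_))
    }
    t_start <- t_end - 24 * 3600
    member <- pv$time > t_start & pv$time <= t_end
    if (!any(member)) {
      return(list(volume_24h = NA_real_, void_count_24h = NA_integer_,
                  usg_24h = NA_real_))
    }
    m <- window_metrics(pv[member, , drop = FALSE])
    list(volume_24h = m$volume_24h, void_count_24h = m$void_count_24h,
         usg_24h = m$weighted_usg)
  }
  metrics <- Map(per_row, assessments$participant_id, assessments$assess_time)
  feats <- dplyr::bind_cols(
    assessments,
    tibble::tibble(
      volume_24h = unname(vapply(metrics, `[[`, numeric(1), "volume_24h")),
      measured_void_count_24h = unname(vapply(metrics, `[[`, integer(1),
                                              "void_count_24h")),
      usg_24h = unname(vapply(metrics, `[[`, numeric(1), "usg_24h"))
    )
  )
  if ("thirst_vas_mm" %in% names(feats)) {
    tp <- thirst_percent(feats$thirst_vas_mm)
    feats$thirst_pct <- tp$percent
    feats$not_thirsty <- tp$not_thirsty
  }
  if ("void_duration_s" %in% names(feats)) {
    feats$long_void <- long_void_flag(feats$void_duration_s)
  }
  if (!is.null(bodymass)) {
    bm <- body_mass_change(bodymass$day1_kg, bodymass$day2_kg,
                           bodymass$day3_kg)
    bm_tbl <- tibble::tibble(
      participant_id = bodymass$participant_id,
      mass_change_pct = bm$percent_change,
      mass_loss_flag = bm$flag_ge_1pct
    )
    feats <- dplyr::left_join(feats, bm_tbl, by = "participant_id")
  }
  tibble::as_tibble(feats)
}
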