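#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set for [generate_cohort()]. Defaults
#' emulate a well-hydrated active occupational cohort: daily fluid intake is
#' log-normal with median ~4.4 L, 24-h urine volume is about half of intake,
#' void count has median 7, and 24-h USG has median ~1.010-1.012.
#'
#' The latent model couples intake to concentration through
#' `usg = 1.012 + intake_usg_slope * (intake - T_sex) / T_sex`, where
#' `T_sex` is the sex-specific intake threshold of the four-item score
#' (2697 mL female, 3697 mL male). Anchoring the coupling at the low USG
#' reference cut-off means the intake marker crosses its own threshold at
#' exactly the concentration where the reference classification flips, so a
#' zero-noise cohort is perfectly classifiable; `intake_usg_slope = 0`
#' decouples all observable markers from the latent concentration.
#'
#' @param n_participants Number of participants (>= 2).
#' @param female_fraction Proportion of females in \[0, 1\].
#' @param seed Integer seed; identical seed + config gives a bit-identical
#'   cohort.
#' @param daily_intake_log_mean,daily_intake_log_sd Log-scale parameters of
#'   the male daily fluid intake distribution (mL); female intake is shifted
#'   by `log(2697/3697)` so both sexes sit identically relative to their
#'   intake thresholds.
#' @param intake_usg_slope Coupling coefficient (unitless, <= 0) between
#'   relative intake and latent 24-h USG. 0 removes all marker-truth
#'   coupling; more negative values strengthen it.
#' @param usg_noise_sd Residual 24-h USG spread (specific-gravity units) not
#'   explained by intake; also scales the per-void USG dispersion and the
#'   first-morning concentration boost, so `0` makes every urine property an
#'   exact function of intake.
#' @param void_rate_per_day Mean void count per 24-h window at the reference
#'   concentration (1.012).
#' @param spot_volume_mean_morning,spot_volume_mean_afternoon Expected spot
#'   void volume (mL) at the median latent concentration for each session.
#' @param color_noise Probability of a one-level urine color misreading.
#' @param self_report_noise Per-marker reporting-error scales: either a
#'   single non-negative scalar multiplying the default scales, or a named
#'   vector with entries `intake`, `voids`, `spot_morning`, `spot_afternoon`,
#'   `duration` (log-scale sd for multiplicative errors; `voids` is the sd,
#'   in voids, of a rounded-Gaussian tally miscount). Defaults are sized so
#'   reported counts correlate ~0.8 with actual container counts and
#'   single-item discrimination stays moderate, as observed in field use of
#'   these instruments.
#' @param sleep_hours Clock hours (start, end) of the overnight block with
#'   no voids.
#' @param start_time Timestamp at which the 32-h collection starts
#'   (default 08:00 local clock).
#' @return A validated list of class `hyd_config`.
#' @export
generator_config <- function(n_participants = 85,
                             female_fraction = 0.12,
                             seed = 1L,
                             daily_intake_log_mean = log(4377),
                             daily_intake_log_sd = 0.48,
                             intake_usg_slope = -0.010,
                             usg_noise_sd = 0.0025,
                             void_rate_per_day = 7,
                             spot_volume_mean_morning = 450,
                             spot_volume_mean_afternoon = 300,
                             color_noise = 0.35,
                             self_report_noise = 1,
                             sleep_hours = c(23, 6),
                             start_time = as.POSIXct("2024-05-06 08:00:00",
                                                     tz = "UTC")) {
  noise_defaults <- c(intake = 0.35, voids = 1.8, spot_morning = 0.35,
                      spot_afternoon = 0.35, duration = 0.20)
  if (is.numeric(self_report_noise) && length(self_report_noise) == 1 &&
      is.null(names(self_report_noise))) {
    self_report_noise <- noise_defaults * self_report_noise
  } else {
    miss <- setdiff(names(noise_defaults), names(self_report_noise))
    full <- c(self_report_noise, noise_defaults[miss])
    self_report_noise <- full[names(noise_defaults)]
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    female_fraction = female_fraction,
    seed = as.integer(seed),
    daily_intake_log_mean = daily_intake_log_mean,
    daily_intake_log_sd = daily_intake_log_sd,
    intake_usg_slope = intake_usg_slope,
    usg_noise_sd = usg_noise_sd,
    void_rate_per_day = void_rate_per_day,
    spot_volume_mean_morning = spot_volume_mean_morning,
    spot_volume_mean_afternoon = spot_volume_mean_afternoon,
    color_noise = color_noise,
    self_report_noise = self_report_noise,
    sleep_hours = sleep_hours,
    start_time = start_time
  )
  validate_config(cfg)
  structure(cfg, class = "hyd_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid generator configuration: `%s` %s",
                          field, msg), call. = FALSE)
  }
  chk(cfg$n_participants >= 2, "n_participants", "must be >= 2")
  chk(cfg$female_fraction >= 0 && cfg$female_fraction <= 1,
      "female_fraction", "must be a proportion in [0, 1]")
  chk(cfg$daily_intake_log_sd > 0, "daily_intake_log_sd",
      "must be strictly positive")
  chk(cfg$intake_usg_slope <= 0, "intake_usg_slope", "must be <= 0")
  chk(cfg$usg_noise_sd >= 0, "usg_noise_sd", "must be non-negative")
  chk(cfg$void_rate_per_day > 0, "void_rate_per_day",
      "must be strictly positive")
  chk(cfg$spot_volume_mean_morning > 0, "spot_volume_mean_morning",
      "must be strictly positive")
  chk(cfg$spot_volume_mean_afternoon > 0, "spot_volume_mean_afternoon",
      "must be strictly positive")
  chk(cfg$color_noise >= 0 && cfg$color_noise <= 1, "color_noise",
      "must be a probability in [0, 1]")
  chk(all(cfg$self_report_noise >= 0), "self_report_noise",
      "scales must be non-negative")
  invisible(cfg)
}

# Sex-specific intake thresholds of the four-item score (mL).
intake_threshold <- function(sex) {
  ifelse(sex == "female", 2697, 3697)
}

usg_clamp <- function(x) pmin(pmax(x, 1.000), 1.040)

# multiplicative log-normal reporting error with unit mean
report_error <- function(n, sdlog) {
  if (sdlog <= 0) return(rep(1, n))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate a synthetic 32-hour urine-collection cohort
#'
#' Simulates participants, their 32-h void streams, fluid diaries,
#' morning/afternoon self-assessment responses, body-mass series and the
#' latent per-window 24-h USG truth. The observable markers (reported
#' intake, reported void count, spot volume, urine color) are noisy
#' monotone functions of the 0.001-quantized systematic concentration, so
#' marker-truth coupling is governed by `intake_usg_slope` and the noise
#' scales; see [generator_config()].
#'
#' @param config A `hyd_config` from [generator_config()].
#' @return A list of class `hyd_cohort` with tibbles `participants`,
#'   `voids`, `diaries`, `assessments`, `bodymass`, `truth` and the
#'   `config` used.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(n_participants = 10, seed = 42))
#' coh$assessments
generate_cohort <- function(config = generator_config()) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  srn <- config$self_report_noise

  ## ---- participants -------------------------------------------------
  id <- sprintf("P%03d", seq_len(n))
  sex <- ifelse(runif(n) < config$female_fraction, "female", "male")
  age <- pmin(pmax(round(exp(rnorm(n, log(27), 0.18))), 18L), 65L)
  height_cm <- round(rnorm(n, ifelse(sex == "female", 165, 178), 7))
  bmi <- round(rnorm(n, 26, 3), 1)
  mass_kg <- round(bmi * (height_cm / 100)^2, 1)
  participants <- tibble::tibble(
    participant_id = id, sex = sex, age = age,
    height_cm = height_cm, body_mass_kg = mass_kg, bmi = bmi,
    race = sample(c("white", "asian", "ai_an", "nh_pi", "multiple"), n,
                  replace = TRUE, prob = c(0.65, 0.23, 0.04, 0.01, 0.07)),
    ethnicity_hispanic = runif(n) < 0.19,
    hire = sample(c("year", "seasonal", "non_wlff"), n, replace = TRUE,
                  prob = c(0.365, 0.365, 0.27)),
    supplement_use = runif(n) < 0.77,
    medicine_use = runif(n) < 0.13,
    alcohol_use = runif(n) < 0.65,
    nicotine_use = runif(n) < 0.39
  )

  ## ---- latent hydration axis ---------------------------------------
  thr <- intake_threshold(sex)
  intake <- rlnorm(n, config$daily_intake_log_mean +
                     ifelse(sex == "female", log(2697 / 3697), 0),
                   config$daily_intake_log_sd)
  m <- usg_clamp(1.012 + config$intake_usg_slope * (intake - thr) / thr)
  # systematic concentration at measurement resolution (USG read to 0.001)
  mq <- round(m, 3)

  z_p <- rnorm(n)
  truth_list <- lapply(c(morning = 1, afternoon = 2), function(k) {
    u <- usg_clamp(mq + config$usg_noise_sd * (0.8 * z_p + 0.6 * rnorm(n)))
    round(u, 3)
  })
  ## overnight concentration boost of the first-morning sample: varies
  ## between participants independently of daily hydration (sleep length,
  ## evening intake), which is what blunts morning spot markers; scaled by
  ## usg_noise_sd so a zero-noise cohort has none
  boost_m <- config$usg_noise_sd * pmax(0, rnorm(n, 2.0, 2.0))

  ## per-window void counts, driven by the systematic concentration
  n_voids <- pmax(2L, as.integer(
    floor(config$void_rate_per_day + (1.012 - mq) / 0.0015)))

  ## ---- spot volumes -------------------------------------------------
  ## calibrated so spot volume crosses 250 mL exactly at mq = 1.012 and
  ## equals the configured session mean at the expected median concentration
  u_ref <- 1.012 + config$intake_usg_slope *
    (exp(config$daily_intake_log_mean) - 3697) / 3697
  steep <- function(mean_w) {
    if (mean_w <= 255 || u_ref >= 1.012) return(0.004)
    (1.012 - u_ref) / log(mean_w / 250)
  }
  s_a <- steep(config$spot_volume_mean_afternoon)
  ## systematic spot volume, saturating at typical bladder capacity (900 mL)
  spot_sys <- pmin(250 * exp(-(mq - 1.012) / s_a), 900)
  ## the first-morning void additionally carries overnight accumulation,
  ## largely independent of daily hydration: this is what makes the morning
  ## volume marker a weak discriminator. Scaled by the morning noise knob so
  ## a zero-noise cohort has none.
  accum_mean <- max(0, config$spot_volume_mean_morning -
                      config$spot_volume_mean_afternoon)
  g_m <- pmin(1, srn[["spot_morning"]] / 0.35)
  accum <- if (accum_mean > 0 && g_m > 0) {
    g_m * rgamma(n, shape = 2, rate = 2 / accum_mean)
  } else {
    numeric(n)
  }
  spot_morning <- pmin(
    spot_sys * report_error(n, srn[["spot_morning"]]) + accum, 1100)
  spot_afternoon <- spot_sys * report_error(n, srn[["spot_afternoon"]])

  ## ---- void stream --------------------------------------------------
  ## windows: morning (0, 24], afternoon (8, 32]; shared segment (8, 24].
  ## Clock: h0 = start_time (08:00), sleep block 23:00-06:00 -> h15-h22.
  shared <- pmin(pmax(1L, as.integer(ceiling(2 * n_voids / 3))),
                 n_voids, n_voids - 1L)
  shared <- pmax(shared, 1L)
  early <- n_voids - shared          # voids in (0, 8]
  late <- n_voids - shared           # voids in (24, 32], incl. spot
  seg_counts <- rbind(early, shared - 1L, 1L, late - 1L, 1L)
  seg_id <- rep(rep(1:5, n), as.vector(seg_counts))
  pid_v <- rep(rep(id, each = 5), as.vector(seg_counts))
  nv <- length(seg_id)
  h_sleep <- (config$sleep_hours[1] - 8) %% 24   # sleep onset, stream hours
  h_wake <- (config$sleep_hours[2] - 8) %% 24    # wake-up, stream hours
  hrs <- numeric(nv)
  hrs[seg_id == 1] <- runif(sum(seg_id == 1), 0, 8)            # day-1 shift
  hrs[seg_id == 2] <- runif(sum(seg_id == 2), 8, h_sleep)      # evening
  hrs[seg_id == 3] <- runif(sum(seg_id == 3), h_wake + 0.5, 23.8)
  hrs[seg_id == 4] <- runif(sum(seg_id == 4), 24, 31)          # day-2 shift
  hrs[seg_id == 5] <- runif(sum(seg_id == 5), 31, 31.9)        # last void

  idx <- match(pid_v, id)
  base_vol <- pmax(60, 0.5 * intake[idx] / n_voids[idx])
  vol <- rgamma(nv, shape = 5, rate = 5 / base_vol)
  vol[seg_id == 3] <- spot_morning[idx[seg_id == 3]]
  vol[seg_id == 5] <- spot_afternoon[idx[seg_id == 5]]

  u_seg <- ifelse(seg_id == 1, truth_list$morning[idx],
           ifelse(seg_id >= 4, truth_list$afternoon[idx],
                  (truth_list$morning[idx] + truth_list$afternoon[idx]) / 2))
  boost <- ifelse(seg_id == 3, boost_m[idx], 0)
  usg_v <- round(usg_clamp(
    u_seg + boost + 0.6 * config$usg_noise_sd * rnorm(nv)), 3)

  voids <- tibble::tibble(
    participant_id = pid_v,
    time = config$start_time + hrs * 3600,
    volume_ml = round(vol, 1),
    usg = usg_v
  ) |>
    dplyr::arrange(.data$participant_id, .data$time)

  ## ---- diaries (periods 0-8 h, 8-24 h, 24-32 h) ---------------------
  diaries <- tibble::tibble(
    participant_id = rep(id, each = 3),
    period = rep(1:3, n),
    start_hour = rep(c(0, 8, 24), n),
    end_hour = rep(c(8, 24, 32), n),
    volume_ml = round(as.vector(rbind(0.35 * intake, 0.65 * intake,
                                      0.35 * intake)), 0)
  )

  ## ---- self-assessments --------------------------------------------
  # tally-counter reporting error: rounded Gaussian miscount (sd in voids),
  # sized so reported vs actual counts correlate ~0.8, as seen in practice
  miscount <- function() {
    as.integer(round(rnorm(n, 0, srn[["voids"]])))
  }
  assess <- function(session) {
    morning <- session == "morning"
    spot_vol <- if (morning) spot_morning else spot_afternoon
    spot_usg <- round(usg_clamp(mq + (if (morning) boost_m else 0)), 3)
    thirst_pct <- pmin(pmax(rnorm(n, if (morning) 36 else 22,
                                  if (morning) 18 else 13), 0), 100)
    distress_pct <- pmin(pmax(0.65 * thirst_pct + rnorm(n, 0, 6), 0), 100)
    flow <- 22 * report_error(n, srn[["duration"]])
    tibble::tibble(
      participant_id = id,
      session = session,
      assess_time = config$start_time + (if (morning) 24 else 32) * 3600,
      sex = sex,
      reported_intake_24h = round(intake * report_error(n, srn[["intake"]])),
      reported_void_count_24h = pmax(0L, n_voids + miscount()),
      spot_volume = round(spot_vol, 1),
      color_score = color_from_usg(spot_usg, config$color_noise),
      thirst_vas_mm = round(thirst_pct * 1.75, 1),
      thirst_distress_mm = round(distress_pct * 1.75, 1),
      void_duration_s = round(spot_vol / flow, 1),
      systolic_bp = round(rnorm(n, if (morning) 125 else 124, 12)),
      diastolic_bp = round(rnorm(n, if (morning) 76 else 73, 9)),
      heart_rate = round(rnorm(n, if (morning) 70 else 74, 10))
    )
  }
  assessments <- dplyr::bind_rows(assess("morning"), assess("afternoon"))

  ## ---- body mass series --------------------------------------------
  bodymass <- tibble::tibble(
    participant_id = id,
    day1_kg = round(mass_kg * (1 + rnorm(n, 0, 0.005)), 2),
    day2_kg = round(mass_kg * (1 + rnorm(n, 0, 0.005)), 2),
    day3_kg = round(mass_kg * (1 + rnorm(n, 0, 0.005)), 2)
  )

  ## ---- truth ---------------------------------------------------------
  truth <- tibble::tibble(
    participant_id = rep(id, 2),
    session = rep(c("morning", "afternoon"), each = n),
    usg_24h = c(truth_list$morning, truth_list$afternoon),
    usg_systematic = rep(mq, 2),
    intake_ml = rep(round(intake), 2),
    void_count = rep(n_voids, 2),
    spot_volume_ml = round(c(spot_morning, spot_afternoon), 1),
    color_score = c(color_from_usg(round(usg_clamp(mq + boost_m), 3), 0),
                    color_from_usg(mq, 0))
  )

  structure(
    list(participants = participants, voids = voids, diaries = diaries,
         assessments = assessments, bodymass = bodymass, truth = truth,
         config = config),
    class = "hyd_cohort"
  )
}

#' @export
print.hyd_cohort <- function(x, ...) {
  cat(sprintf(
    "<hyd_cohort> %d participants, %d voids over 32 h, seed %d\n",
    nrow(x$participants), nrow(x$voids), x$config$seed))
  invisible(x)
}
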