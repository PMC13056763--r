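test_that("hourly stream splits into two half-open 24-h windows overlapping 16 h", {
  voids <- mk_voids(1:32)
  w <- extract_windows(voids, c(t0 + 24 * 3600, t0 + 32 * 3600))
  expect_equal(nrow(w$morning$voids), 24)   # voids in (0, 24]
  expect_equal(nrow(w$afternoon$voids), 24) # voids in (8, 32]
  overlap <- intersect(w$morning$voids$time, w$afternoon$voids$time)
  expect_equal(length(overlap), 16)         # voids in (8, 24]
  expect_equal(as.numeric(difftime(w$morning$end, w$morning$start,
                                   units = "hours")), 24)
})

test_that("a void at exactly t - 24 h is excluded (half-open boundary)", {
  voids <- mk_voids(c(0, 12))
  w <- extract_windows(voids, c(t0 + 24 * 3600, t0 + 32 * 3600))
  expect_equal(nrow(w$morning$voids), 1)  # only the h = 12 void
  # a void at exactly the assessment time is included
  voids2 <- mk_voids(c(12, 24))
  w2 <- extract_windows(voids2, c(t0 + 24 * 3600, t0 + 32 * 3600))
  expect_equal(nrow(w2$morning$voids), 2)
  expect_error(extract_windows(mk_voids(numeric(0)), c(t0, t0)), "empty")
})

test_that("partial-coverage flag marks assessments within 24 h of the first void", {
  voids <- mk_voids(c(20, 22))
  w <- extract_windows(voids, c(t0 + 24 * 3600, t0 + 32 * 3600))
  expect_true(w$morning$partial)
  w_full <- extract_windows(mk_voids(1:32),
                            c(t0 + 32 * 3600, t0 + 32 * 3600))
  expect_false(w_full$afternoon$partial)
})

test_that("weighted USG equals the volume-weighted mean", {
  expect_equal(weighted_usg(tibble::tibble(usg = c(1.010, 1.020),
                                           volume_ml = c(1000, 1000))),
               1.015)
  expect_equal(weighted_usg(tibble::tibble(usg = 1.013, volume_ml = 350)),
               1.013)
  # independent hand computation of the formula:
  # (1.005*300 + 1.015*600 + 1.030*100) / 1000 = 1013.5 / 1000
  w <- tibble::tibble(usg = c(1.005, 1.015, 1.030),
                      volume_ml = c(300, 600, 100))
  expect_equal(weighted_usg(w), 1.0135, tolerance = 1e-15)
  expect_error(weighted_usg(tibble::tibble(usg = numeric(0),
                                           volume_ml = numeric(0))), "empty")
  expect_error(weighted_usg(tibble::tibble(usg = 1.01, volume_ml = 0)),
               "positive")
})

test_that("weighted USG is mixture-consistent and bounded by member USG", {
  set.seed(404)
  for (i in 1:200) {
    k <- sample(2:10, 1)
    w <- tibble::tibble(usg = round(runif(k, 1.001, 1.035), 3),
                        volume_ml = runif(k, 30, 800))
    u <- weighted_usg(w)
    expect_gte(u, min(w$usg))
    expect_lte(u, max(w$usg))
    # split one void into two of the same USG, volumes summing to it
    j <- sample(k, 1)
    frac <- runif(1, 0.1, 0.9)
    w2 <- dplyr::bind_rows(
      w[-j, ],
      tibble::tibble(usg = w$usg[j],
                     volume_ml = w$volume_ml[j] * c(frac, 1 - frac)))
    expect_equal(weighted_usg(w2), u, tolerance = 1e-12)
  }
})

test_that("window metrics summarise volume, count and concentration", {
  m <- window_metrics(mk_voids(c(2, 4, 6), volume = 200))
  expect_equal(m$volume_24h, 600)
  expect_equal(m$void_count_24h, 3)
  expect_error(window_metrics(mk_voids(numeric(0))), "empty")
})

test_that("thirst VAS percentage uses the 175-mm anchor, 40% boundary inclusive", {
  expect_equal(thirst_percent(0)$percent, 0)
  expect_equal(thirst_percent(175)$percent, 100)
  tp <- thirst_percent(70)   # 70/175 by hand = 40.0%
  expect_equal(tp$percent, 40)
  expect_true(tp$not_thirsty)
  expect_false(thirst_percent(70.2)$not_thirsty)
  expect_error(thirst_percent(-1), "non-negative")
})

test_that("body-mass change compares Day 2 against the Day 1/3 average", {
  bm <- body_mass_change(80, 80, 80)
  expect_equal(bm$percent_change, 0)
  expect_false(bm$flag_ge_1pct)
  bm2 <- body_mass_change(80, 79.2, 80)   # -0.8/80 = -1.0% by hand
  expect_equal(bm2$percent_change, -1)
  expect_true(bm2$flag_ge_1pct)            # boundary inclusive
  bm3 <- body_mass_change(80, 80.8, 80)
  expect_equal(bm3$percent_change, 1)
  expect_false(bm3$flag_ge_1pct)           # gains never flag
  expect_error(body_mass_change(0, 80, 80), "positive")
})

test_that("long-void flag is inclusive at 16 s", {
  expect_true(long_void_flag(16))
  expect_false(long_void_flag(15.9))
  expect_false(long_void_flag(0))
  expect_error(long_void_flag(-2), "non-negative")
})

test_that("build_features yields one complete row per assessment", {
  coh <- generate_cohort(generator_config(n_participants = 20, seed = 2))
  f <- build_features(coh$voids, coh$assessments, coh$bodymass)
  expect_equal(nrow(f), nrow(coh$assessments))
  expect_true(all(!is.na(f$usg_24h)))
  expect_true(all(c("volume_24h", "measured_void_count_24h", "thirst_pct",
                    "long_void", "mass_change_pct") %in% names(f)))
})
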