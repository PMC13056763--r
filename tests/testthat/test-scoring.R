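test_that("all 16 boundary combinations force the expected items, total and class", {
  grid <- expand.grid(i1 = 0:1, i2 = 0:1, i3 = 0:1, i4 = 0:1)
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    rec <- mk_record(
      sex = "male",
      intake = if (g$i1 == 0) 3697 else 3696,  # threshold met vs just missed
      count  = if (g$i2 == 0) 7 else 6,
      spot   = if (g$i3 == 0) 250 else 249,
      color  = if (g$i4 == 0) 2 else 3
    )
    s <- score_items(rec)
    expect_equal(unlist(s[1, c("intake_item", "frequency_item",
                               "volume_item", "color_item")],
                        use.names = FALSE),
                 c(g$i1, g$i2, g$i3, g$i4))
    expect_equal(s$total, g$i1 + g$i2 + g$i3 + g$i4)
    expect_equal(s$predicted_class,
                 if (s$total >= 2) "high_concentration" else "low_concentration")
  }
})

test_that("intake threshold is sex-specific", {
  s_f <- score_items(mk_record(sex = "female", intake = 2697, spot = 100,
                               count = 8, color = 3))
  expect_equal(unlist(s_f[1, 1:4], use.names = FALSE), c(0, 0, 1, 1))
  expect_equal(s_f$total, 2)
  expect_equal(s_f$predicted_class, "high_concentration")
  # 2697 mL meets the female threshold but misses the male one
  expect_equal(score_items(mk_record(sex = "male", intake = 2697))$intake_item, 1)
})

test_that("scoring aborts on missing markers or unknown sex", {
  rec <- mk_record(); rec$spot_volume <- NA_real_
  expect_error(score_items(rec), "missing")
  rec2 <- mk_record(); rec2$color_score <- NULL
  expect_error(score_items(rec2), "missing")
  expect_error(score_items(mk_record(sex = "unknown")), "sex")
})

test_that("improving any single marker never increases the total score", {
  set.seed(77)
  for (i in 1:100) {
    rec <- mk_record(sex = sample(c("female", "male"), 1),
                     intake = runif(1, 1000, 6000),
                     count = sample(1:14, 1),
                     spot = runif(1, 20, 800),
                     color = sample(1:7, 1))
    base <- score_items(rec)$total
    better <- list(
      utils::modifyList(rec, list(reported_intake_24h = rec$reported_intake_24h + 500)),
      utils::modifyList(rec, list(reported_void_count_24h = rec$reported_void_count_24h + 1)),
      utils::modifyList(rec, list(spot_volume = rec$spot_volume + 100)),
      utils::modifyList(rec, list(color_score = max(1, rec$color_score - 1)))
    )
    for (b in better) expect_lte(score_items(b)$total, base)
  }
})

test_that("reference labels flip exactly at the two cut-offs", {
  expect_equal(reference_label(1.012, "low"), "low_concentration")
  expect_equal(reference_label(1.013, "low"), "high_concentration")
  expect_equal(reference_label(1.019, "high"), "low_concentration")
  expect_equal(reference_label(1.020, "high"), "high_concentration")
  # float-representation robustness at the boundary
  expect_equal(reference_label(1.0125 - 0.0005, "low"), "low_concentration")
  expect_error(reference_label(0.999), "range")
})

test_that("classify_cohort excludes exactly the incomplete records", {
  coh <- generate_cohort(generator_config(n_participants = 30, seed = 14))
  f <- build_features(coh$voids, coh$assessments)
  f$spot_volume[c(2, 9)] <- NA
  f$color_score[31] <- NA
  cl <- classify_cohort(f, usg_cutoff = "low")
  expect_equal(nrow(cl), nrow(f) - 3)
  expect_equal(nrow(attr(cl, "incomplete")), 3)
  # duplicate keys are an error
  f2 <- dplyr::bind_rows(f, f[1, ])
  expect_error(classify_cohort(f2), "duplicate")
})

test_that("classification tables round-trip through CSV unchanged", {
  coh <- generate_cohort(generator_config(n_participants = 15, seed = 6))
  f <- build_features(coh$voids, coh$assessments)
  cl <- classify_cohort(f, usg_cutoff = "low")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cl, path, progress = FALSE)
  back <- readr::read_csv(path, show_col_types = FALSE)
  cols <- c("intake_item", "frequency_item", "volume_item", "color_item",
            "total", "predicted_class", "reference")
  expect_equal(as.data.frame(back[cols]), as.data.frame(cl[cols]),
               ignore_attr = TRUE)
})
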