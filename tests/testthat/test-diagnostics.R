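test_that("contingency cross-tabulates against the declared positive class", {
  ct <- contingency(rep("pos", 5), rep("pos", 5), positive = "pos")
  expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), c(5, 0, 0, 0))
  # label vectors reconstructing the published morning/low model counts
  pred <- c(rep("high", 32 + 12), rep("low", 16 + 20))
  ref <- c(rep("high", 32), rep("low", 12), rep("high", 16), rep("low", 20))
  ct2 <- contingency(pred, ref, positive = "high")
  expect_equal(c(ct2$tp, ct2$tn, ct2$fp, ct2$fn), c(32, 20, 12, 16))
  set.seed(1)
  p <- sample(c("a", "b"), 100, TRUE); r <- sample(c("a", "b"), 100, TRUE)
  ct3 <- contingency(p, r, positive = "a")
  expect_equal(ct3$total, 100)
  expect_error(contingency(p[1:5], r, positive = "a"), "length")
  expect_error(contingency(p, r, positive = "zzz"), "absent")
})

test_that("rates follow the TP/FN and TN/FP definitions with one-decimal reporting", {
  r <- sens_spec_acc(new_contingency(tp = 32, fp = 12, fn = 16, tn = 20))
  expect_equal(r$report$sensitivity, 66.7)   # 32/48
  expect_equal(r$report$specificity, 62.5)   # 20/32
  r2 <- sens_spec_acc(new_contingency(tp = 28, fp = 7, fn = 10, tn = 22))
  expect_equal(r2$report$sensitivity, 73.7)
  expect_equal(r2$report$specificity, 75.9)
  r3 <- sens_spec_acc(new_contingency(tp = 50, fp = 0, fn = 0, tn = 50))
  expect_equal(unlist(r3$report), c(sensitivity = 100, specificity = 100,
                                    accuracy = 100))
  # zero denominator yields an undefined marker, not an error
  r4 <- sens_spec_acc(new_contingency(tp = 0, fp = 3, fn = 0, tn = 7))
  expect_true(is.na(r4$sensitivity))
  expect_false(is.na(r4$specificity))
})

test_that("rank AUC matches exhaustive pair counting, trapezoid and pROC", {
  expect_equal(auc_rank(c(1, 2, 10, 11), c("n", "n", "p", "p"), "p"), 1)
  expect_equal(auc_rank(rep(3, 10), rep(c("n", "p"), 5), "p"), 0.5)
  # frozen from the pair-counting oracle: pos scores {2, 4} vs neg {0, 1, 3}
  expect_equal(auc_rank(0:4, c(0, 0, 1, 0, 1), positive = 1), 5 / 6)
  set.seed(31)
  for (i in 1:30) {
    n <- sample(10:120, 1)
    scores <- sample(0:6, n, replace = TRUE)  # heavy ties
    labels <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    a <- auc_rank(scores, labels, "b")
    expect_equal(a, auc_pairs(scores, labels, "b"), tolerance = 1e-12)
    expect_equal(a, auc_trapezoid(scores, labels, "b"), tolerance = 1e-12)
    ap <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("a", "b"),
      direction = "<", quiet = TRUE)))
    expect_equal(a, ap, tolerance = 1e-12)
  }
  expect_error(auc_rank(1:4, rep("a", 4), "a"), "both classes")
})

test_that("AUC interpretation bands follow the stated intervals", {
  expect_equal(auc_band(c(0.95, 0.90, 0.89, 0.80, 0.79, 0.70, 0.69)),
               c("excellent", "excellent", "good", "good", "fair", "fair",
                 "below fair"))
})

test_that("rank-biserial correlation equals the signed-rank-sum ratio", {
  expect_equal(rank_biserial(c(2, 5, 1))$value, 1)
  expect_equal(rank_biserial(c(4, -4, 2, -2))$value, 0)
  # hand-computed: |d| = (3,1,2,2,5) -> ranks (4,1,2.5,2.5,5);
  # W+ = 4+2.5+5 = 11.5, W- = 1+2.5 = 3.5, r_rb = 8/15
  rb <- rank_biserial(c(3, -1, 2, -2, 5))
  expect_equal(rb$w_plus, 11.5)
  expect_equal(rb$w_minus, 3.5)
  expect_equal(rb$value, 8 / 15)
  expect_equal(rb$magnitude_band, "large")
  # zeros are dropped; all-zero is undefined
  expect_equal(rank_biserial(c(0, 0, 3))$value, 1)
  expect_true(is.na(rank_biserial(c(0, 0))$value))
})

test_that("rank-biserial sign matches the median difference under symmetric noise", {
  set.seed(52)
  for (shift in c(-0.8, 0.8)) {
    d <- rnorm(200, mean = shift)
    expect_equal(sign(rank_biserial(d)$value), sign(median(d)))
  }
})

test_that("Cramer's V uses the uncorrected chi-square and the smaller dimension", {
  expect_equal(cramers_v(diag(c(10, 10)))$value, 1)
  indep <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(cramers_v(indep)$value, 0)
  # hand computation: chi2 = 15.428571..., V = sqrt(chi2 / 60) = 0.50709255
  v <- cramers_v(matrix(c(20, 5, 10, 25), 2))
  expect_equal(v$chi2, 108 / 7, tolerance = 1e-12)
  expect_equal(v$value, sqrt(108 / 7 / 60), tolerance = 1e-12)
  expect_equal(v$magnitude_band, "large")
  # invariant under row/column permutation
  m <- matrix(c(12, 3, 8, 30, 6, 11), 2)
  expect_equal(cramers_v(m[, c(2, 1, 3)])$value, cramers_v(m)$value)
  expect_equal(cramers_v(m[c(2, 1), ])$value, cramers_v(m)$value)
  expect_error(cramers_v(matrix(c(5, 0, 7, 0), 2)), "margin")
})

test_that("Spearman correlation is Pearson on mid-ranks", {
  x <- c(3, 9, 1, 5, 7)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  set.seed(9)
  a <- sample(1:8, 40, TRUE); b <- a + rnorm(40)
  expect_equal(spearman_rho(a, b), cor(a, b, method = "spearman"))
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_error(spearman_rho(1:2, 1:2), "length")
})

test_that("test dispatch covers rank, chi-square and exact modes", {
  same <- c(3, 5, 7)
  w <- assoc_test(same, same, mode = "wilcoxon_signed_rank")
  expect_true(is.na(w$p_value))
  expect_match(w$note, "undefined")
  # Fisher on [[5,0],[0,5]]: only the two extreme tables are as likely,
  # p = 2 / choose(10, 5)
  f <- assoc_test(matrix(c(5, 0, 0, 5), 2), mode = "fisher_exact")
  expect_equal(f$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  mw <- assoc_test(11:20, 1:10, mode = "mann_whitney")
  expect_equal(unname(mw$statistic), 100)  # U = n1 * n2 on full separation
  tab <- matrix(c(20, 5, 10, 25), 2)
  cs <- assoc_test(tab, mode = "chi_square")
  expect_equal(cs$p_value,
               stats::chisq.test(tab, correct = FALSE)$p.value)
  expect_error(assoc_test(matrix(1:3, 1), mode = "chi_square"), "table")
})

test_that("evaluate_model reports the model above its individual items on coupled data", {
  cfg <- generator_config(n_participants = 200, seed = 33,
                          intake_usg_slope = -0.02, usg_noise_sd = 0,
                          color_noise = 0, self_report_noise = 0)
  r <- run_pipeline(cfg, select = FALSE)
  rep <- r$report
  expect_equal(rep$auc[rep$variable == "model"], 1.0)
  expect_true(all(rep$auc <= rep$auc[rep$variable == "model"]))
  expect_equal(rep$accuracy[rep$variable == "model"], 100)
})
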