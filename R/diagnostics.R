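#' Build a 2x2 contingency table from paired class labels
#'
#' Cross-tabulates predicted against reference labels for a declared
#' positive class. `tp` counts agreement on the positive class, `tn`
#' agreement on the negative class.
#'
#' @param predicted,reference Equal-length label vectors drawn from the
#'   same two-class alphabet.
#' @param positive The positive class label.
#' @return Object of class `contingency_2x2`: list with `tp`, `fp`, `fn`,
#'   `tn`, `positive`, `total`.
#' @export
#' @examples
#' contingency(c("a", "a", "b"), c("a", "b", "b"), positive = "a")
contingency <- function(predicted, reference, positive) {
  if (length(predicted) != length(reference)) {
    stop("`predicted` and `reference` must have equal length", call. = FALSE)
  }
  alphabet <- unique(c(predicted, reference))
  if (length(alphabet) > 2) {
    stop("labels must come from a two-class alphabet", call. = FALSE)
  }
  if (!positive %in% alphabet) {
    stop("positive class ", shQuote(positive), " absent from labels",
         call. = FALSE)
  }
  p <- predicted == positive
  r <- reference == positive
  new_contingency(tp = sum(p & r), fp = sum(p & !r),
                  fn = sum(!p & r), tn = sum(!p & !r), positive = positive)
}

#' Construct a contingency table from counts
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @param positive Optional positive-class label, for bookkeeping.
#' @return Object of class `contingency_2x2`.
#' @export
new_contingency <- function(tp, fp, fn, tn, positive = "positive") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(is.na(counts))) {
    stop("counts must be non-negative", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) stop("empty contingency table", call. = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 positive = positive, total = total),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<2x2> positive = %s | TP %d  FP %d  FN %d  TN %d (n = %d)\n",
              x$positive, x$tp, x$fp, x$fn, x$tn, x$total))
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a 2x2 table
#'
#' Percentages: sensitivity `100*tp/(tp+fn)`, specificity
#' `100*tn/(tn+fp)`, accuracy `100*(tp+tn)/total`. Raw (unrounded) values
#' are returned; `report` holds the same values rounded half-up to one
#' decimal, the conventional reporting precision. A zero denominator
#' yields `NA` (an explicit "undefined rate" marker), never an error, so
#' per-item tables with empty cells stay printable.
#'
#' @param ct A `contingency_2x2`.
#' @return List with `sensitivity`, `specificity`, `accuracy` (raw
#'   percentages) and `report` (one-decimal versions).
#' @export
#' @examples
#' sens_spec_acc(new_contingency(tp = 32, fp = 12, fn = 16, tn = 20))
sens_spec_acc <- function(ct) {
  stopifnot(inherits(ct, "contingency_2x2"))
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- list(
    sensitivity = rate(ct$tp, ct$tp + ct$fn),
    specificity = rate(ct$tn, ct$tn + ct$fp),
    accuracy = rate(ct$tp + ct$tn, ct$total)
  )
  out$report <- lapply(out, round_half_up, digits = 1)
  out
}

#' Rank-based AUC (Mann-Whitney formulation)
#'
#' Area under the empirical ROC curve computed from mid-ranks:
#' `AUC = (R1 - n1(n1+1)/2) / (n1*n0)` where `R1` is the rank sum of the
#' positive-class scores. Ties receive mid-ranks, so the value equals the
#' trapezoidal area under the empirical ROC and the probability that a
#' random positive outranks a random negative (ties counted half). Higher
#' scores must indicate the positive class.
#'
#' @param scores Numeric (or ordinal) predictor.
#' @param labels Class labels, same length.
#' @param positive Positive class label.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_rank(c(0.1, 0.4, 0.8), c("neg", "pos", "pos"), positive = "pos")
auc_rank <- function(scores, labels, positive) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)  # mid-ranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Interpretation band of an AUC
#'
#' Excellent >= 0.90, good 0.80-0.89, fair 0.70-0.79, below fair otherwise.
#'
#' @param auc AUC value(s) in \[0, 1\].
#' @return Character vector.
#' @export
auc_band <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1, na.rm = TRUE))
  dplyr::case_when(
    is.na(auc) ~ NA_character_,
    auc >= 0.90 ~ "excellent",
    auc >= 0.80 ~ "good",
    auc >= 0.70 ~ "fair",
    TRUE ~ "below fair"
  )
}

#' Rank-biserial correlation for paired differences
#'
#' Effect size of the Wilcoxon signed-rank test:
#' `r_rb = (W+ - W-) / (W+ + W-)`, where `W+` and `W-` are the rank sums
#' of the positive and negative differences (zeros dropped, mid-ranks for
#' tied magnitudes). Banded small >= 0.1, medium >= 0.3, large >= 0.5 (on
#' the magnitude).
#'
#' @param paired_diffs Signed differences.
#' @return List of class `effect_size` with `kind`, `value`, `w_plus`,
#'   `w_minus`, `n_nonzero`, `magnitude_band`. All-zero differences give
#'   `value = NA` (undefined marker).
#' @export
#' @examples
#' rank_biserial(c(3, -1, 2, -2, 5))
rank_biserial <- function(paired_diffs) {
  d <- paired_diffs[!is.na(paired_diffs)]
  d <- d[d != 0]
  if (length(d) == 0) {
    return(structure(list(kind = "rank_biserial", value = NA_real_,
                          w_plus = 0, w_minus = 0, n_nonzero = 0L,
                          magnitude_band = NA_character_),
                     class = "effect_size"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  value <- (w_plus - w_minus) / (w_plus + w_minus)
  structure(list(kind = "rank_biserial", value = value,
                 w_plus = w_plus, w_minus = w_minus,
                 n_nonzero = length(d),
                 magnitude_band = rb_band(abs(value))),
            class = "effect_size")
}

rb_band <- function(a) {
  dplyr::case_when(a >= 0.5 ~ "large", a >= 0.3 ~ "medium",
                   a >= 0.1 ~ "small", TRUE ~ "negligible")
}

#' Cramer's V association for an r x c table
#'
#' `V = sqrt(chi2 / (n * (k - 1)))` with the plain Pearson chi-square
#' statistic (no continuity correction) and `k` the smaller table
#' dimension. Banded small < 0.1, medium 0.1-0.3, large > 0.3.
#'
#' @param tab Matrix (or table) of counts, at least 2x2, with no zero
#'   margins.
#' @return List of class `effect_size` with `value`, `chi2`, `n`, `k`,
#'   `magnitude_band`.
#' @export
#' @examples
#' cramers_v(matrix(c(20, 5, 10, 25), 2))
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("table must be at least 2x2", call. = FALSE)
  }
  n <- sum(tab)
  if (n <= 0) stop("empty table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row/column margin", call. = FALSE)
  }
  chi2 <- suppressWarnings(
    unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  k <- min(dim(tab))
  value <- sqrt(chi2 / (n * (k - 1)))
  band <- if (value > 0.3) "large" else if (value >= 0.1) "medium" else "small"
  structure(list(kind = "cramers_v", value = value, chi2 = chi2,
                 n = n, k = k, magnitude_band = band),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size %s> %.4f (%s)\n", x$kind, x$value,
              x$magnitude_band %||% "undefined"))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. Constant input yields `NA`
#' (undefined marker) rather than an error.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return Correlation in \[-1, 1\], or `NA` if either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(rank(x), rank(y))
}

#' Two-sample and contingency tests used in the evaluation chain
#'
#' Thin dispatch over the standard tests: Wilcoxon signed-rank (paired)
#' and Mann-Whitney U with the normal approximation and tie correction
#' (two-sided), Pearson chi-square, and Fisher's exact test (exact
#' enumeration on 2x2 tables). Continuity correction for the rank and
#' chi-square tests is off by default and available via `correct`.
#'
#' @param x First sample, or a contingency matrix for the categorical
#'   modes.
#' @param y Second sample (ignored for matrix input).
#' @param mode One of `"wilcoxon_signed_rank"`, `"mann_whitney"`,
#'   `"chi_square"`, `"fisher_exact"`.
#' @param correct Apply continuity correction where applicable.
#' @return List with `statistic`, `p_value` and `note` (`"undefined"`
#'   when a paired test has no nonzero differences).
#' @export
assoc_test <- function(x, y = NULL,
                       mode = c("wilcoxon_signed_rank", "mann_whitney",
                                "chi_square", "fisher_exact"),
                       correct = FALSE) {
  mode <- match.arg(mode)
  if (mode %in% c("chi_square", "fisher_exact")) {
    tab <- if (is.matrix(x) || is.table(x)) as.matrix(x) else table(x, y)
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      stop("categorical tests need an r x c table with r, c >= 2",
           call. = FALSE)
    }
    if (mode == "chi_square") {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    } else {
      ht <- stats::fisher.test(tab)
    }
    return(list(statistic = unname(ht$statistic %||% NA_real_),
                p_value = ht$p.value, note = NA_character_))
  }
  if (is.null(y)) stop("two samples required for rank tests", call. = FALSE)
  if (mode == "wilcoxon_signed_rank") {
    if (length(x) != length(y)) {
      stop("paired test needs equal-length samples", call. = FALSE)
    }
    if (all(x - y == 0, na.rm = TRUE)) {
      return(list(statistic = NA_real_, p_value = NA_real_,
                  note = "undefined: no nonzero paired differences"))
    }
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                         correct = correct))
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = correct))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       note = NA_character_)
}

#' Evaluate the four-item model and its individual items on a classified
#' cohort
#'
#' Mirrors the standard reporting layout: one row for the graded model
#' (AUC over the 0-4 total score, binary prediction at total >= 2) and one
#' row per item (AUC over the 0/1 item, the item itself as prediction),
#' each with sensitivity/specificity/accuracy and TP/TN/FP/FN counts.
#' Because an item score of 1 means "suggests high concentration", scores
#' are reversed internally when the declared positive class is
#' `low_concentration`.
#'
#' @param classified Output of [classify_cohort()].
#' @param positive Positive class for the contingency tables; defaults to
#'   `"high_concentration"` for the low USG cut-off and
#'   `"low_concentration"` for the high cut-off (where the
#'   low-concentration group is the printed positive margin).
#' @return A tibble with one row per variable: `variable`, `auc`,
#'   `auc_band`, `sensitivity`, `specificity`, `accuracy` (one-decimal
#'   percentages), `tp`, `tn`, `fp`, `fn`.
#' @export
evaluate_model <- function(classified, positive = NULL) {
  cutoff <- attr(classified, "usg_cutoff") %||% "low"
  if (is.null(positive)) {
    positive <- if (cutoff == "low") "high_concentration" else
      "low_concentration"
  }
  ref <- classified$reference
  vars <- list(
    model = list(score = classified$total,
                 predicted = classified$predicted_class),
    intake = list(score = classified$intake_item),
    frequency = list(score = classified$frequency_item),
    volume = list(score = classified$volume_item),
    color = list(score = classified$color_item)
  )
  rows <- lapply(names(vars), function(v) {
    sc <- vars[[v]]$score
    pred <- vars[[v]]$predicted %||%
      ifelse(sc >= 1, "high_concentration", "low_concentration")
    oriented <- if (positive == "high_concentration") sc else -sc
    a <- auc_rank(oriented, ref, positive)
    ct <- contingency(pred, ref, positive)
    r <- sens_spec_acc(ct)
    tibble::tibble(
      variable = v, auc = a, auc_band = auc_band(a),
      sensitivity = r$report$sensitivity,
      specificity = r$report$specificity,
      accuracy = r$report$accuracy,
      tp = ct$tp, tn = ct$tn, fp = ct$fp, fn = ct$fn
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "positive") <- positive
  attr(out, "usg_cutoff") <- cutoff
  out
}
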