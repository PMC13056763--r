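#' Fit a binary logistic regression with separation reporting
#'
#' Maximum-likelihood fit via iteratively reweighted least squares
#' (`stats::glm`, binomial logit; convergence tolerance 1e-8, at most 100
#' iterations). Quasi-complete separation is detected (fitted
#' probabilities numerically 0/1 together with runaway coefficients) and
#' reported as a flag instead of silently diverging.
#'
#' @param data Data frame of predictors.
#' @param outcome Binary outcome: logical, 0/1, or a two-level factor.
#' @param terms Character vector of predictor columns (default: all).
#' @return List with `coefficients` (tibble: term, estimate, se,
#'   statistic, p_value, odds_ratio, ci_low, ci_high), `loglik`,
#'   `converged`, `separation` and the underlying `fit`.
#' @export
fit_logistic <- function(data, outcome, terms = names(data)) {
  y <- outcome
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  df <- data.frame(.y = y)
  ## logicals as 0/1; categoricals reference-coded with the most frequent
  ## category as reference level
  for (cn in terms) {
    v <- data[[cn]]
    if (length(v) != length(y)) {
      stop("predictor ", shQuote(cn), " does not match the outcome length",
           call. = FALSE)
    }
    if (is.logical(v)) {
      v <- as.integer(v)
    } else if (is.character(v) || is.factor(v)) {
      tab <- sort(table(v), decreasing = TRUE)
      v <- factor(v, levels = names(tab))
    }
    df[[cn]] <- v
  }
  if (nrow(df) <= length(terms) + 1) {
    stop("need n > p observations", call. = FALSE)
  }
  form <- if (length(terms)) {
    stats::reformulate(sprintf("`%s`", terms), response = ".y")
  } else {
    .y ~ 1
  }
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  eta_extreme <- any(fitted(fit) < 1e-6 | fitted(fit) > 1 - 1e-6)
  separation <- eta_extreme && any(abs(coef(fit)) > 8, na.rm = TRUE)
  sm <- summary(fit)$coefficients
  est <- sm[, 1]; se <- sm[, 2]
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = est, se = se,
    statistic = sm[, 3], p_value = sm[, 4],
    odds_ratio = exp(est),
    ci_low = exp(est - 1.96 * se),
    ci_high = exp(est + 1.96 * se)
  )
  list(coefficients = coefs,
       loglik = as.numeric(stats::logLik(fit)),
       converged = fit$converged, separation = separation, fit = fit)
}

# p-value of `term` in the model base + covariates + term. Wald by
# default; under quasi-separation the Wald statistic collapses
# (Hauck-Donner), so the likelihood-ratio p against the model without
# `term` is used instead.
term_p <- function(data, outcome, term, base, covariates) {
  terms <- unique(c(base, covariates, term))
  fl <- tryCatch(fit_logistic(data, outcome, terms), error = function(e) NULL)
  if (is.null(fl)) return(NA_real_)
  row <- coef_rows(fl$coefficients, term)
  if (nrow(row) == 0 || all(is.na(row$p_value))) return(NA_real_)
  if (!fl$separation) return(min(row$p_value, na.rm = TRUE))
  base_terms <- setdiff(terms, term)
  fl0 <- tryCatch(fit_logistic(data, outcome, base_terms),
                  error = function(e) NULL)
  if (is.null(fl0)) return(min(row$p_value, na.rm = TRUE))
  stat <- max(0, 2 * (fl$loglik - fl0$loglik))
  stats::pchisq(stat, df = nrow(row), lower.tail = FALSE)
}

# coefficient rows belonging to a model term (factor terms expand to
# term + level labels)
coef_rows <- function(coefs, term) {
  hit <- coefs$term == term | coefs$term == sprintf("`%s`", term) |
    (startsWith(coefs$term, term) & coefs$term != "(Intercept)")
  coefs[hit, , drop = FALSE]
}

#' Stepwise logistic variable selection
#'
#' The exploratory model-building procedure: forward steps add, among the
#' remaining candidates, the one with the smallest Wald p-value at or
#' below `entry_p`; after every addition, backward steps remove any
#' retained candidate whose p-value has risen above `stay_p`. Covariates
#' are forced into every model during stepping; in the reported final
#' model, covariates not significant at `stay_p` are dropped (mirroring
#' the usual report that no adjustment covariate reached significance).
#' Ties in p-values are broken by the declared candidate order. Visited
#' candidate sets are tracked so the procedure terminates without cycling.
#'
#' Statistical retention is the only rule implemented; `include` forces
#' markers into the model for the judgment-based "practically relevant"
#' step.
#'
#' @param data Data frame holding candidates and covariates.
#' @param outcome Binary outcome vector.
#' @param candidates Character vector of candidate marker columns
#'   (constant columns are dropped before selection).
#' @param covariates Character vector of adjustment columns.
#' @param entry_p Forward entry threshold (default 0.10).
#' @param stay_p Backward retention threshold (default 0.05).
#' @param include Markers to force-keep regardless of p-value.
#' @return List of class `selection_result`: `retained` (character),
#'   `entered` (all markers that ever entered during forward steps),
#'   `coefficients` (final-model tibble with odds ratios and CIs),
#'   `model_auc` (AUC of the final linear predictor against the outcome),
#'   `separation`, `dropped_constant`.
#' @export
stepwise_select <- function(data, outcome, candidates,
                            covariates = character(),
                            entry_p = 0.10, stay_p = 0.05,
                            include = character()) {
  stopifnot(entry_p > 0, entry_p < 1, stay_p > 0, stay_p < 1,
            entry_p >= stay_p)
  if (length(candidates) == 0) stop("no candidates given", call. = FALSE)
  constant <- vapply(candidates, function(cn) {
    v <- data[[cn]]
    length(unique(v[!is.na(v)])) < 2
  }, logical(1))
  dropped_constant <- candidates[constant]
  candidates <- candidates[!constant]
  y <- outcome
  if (is.factor(y)) y <- as.integer(y) - 1L

  current <- include
  entered <- character()
  visited <- character()
  repeat {
    sig <- paste(sort(current), collapse = "|")
    if (sig %in% visited) break
    visited <- c(visited, sig)
    ## forward
    remaining <- setdiff(candidates, current)
    if (length(remaining)) {
      pvals <- vapply(remaining, function(cn) {
        term_p(data, y, cn, current, covariates)
      }, numeric(1))
      ok <- !is.na(pvals) & pvals <= entry_p
      if (any(ok)) {
        best <- remaining[ok][which.min(pvals[ok])]
        current <- c(current, best)
        entered <- union(entered, best)
      }
    }
    ## backward: re-examine retained (non-forced) candidates
    repeat {
      removable <- setdiff(current, include)
      if (!length(removable)) break
      fl <- tryCatch(
        fit_logistic(data, y, unique(c(current, covariates))),
        error = function(e) NULL)
      if (is.null(fl)) break
      ps <- vapply(removable, function(cn) {
        if (fl$separation) {
          return(term_p(data, y, cn, setdiff(current, cn), covariates))
        }
        row <- coef_rows(fl$coefficients, cn)
        if (nrow(row) == 0) NA_real_ else min(row$p_value, na.rm = TRUE)
      }, numeric(1))
      worst <- which.max(ifelse(is.na(ps), 1, ps))
      if (is.na(ps[worst]) || ps[worst] > stay_p) {
        current <- setdiff(current, removable[worst])
      } else {
        break
      }
    }
    remaining <- setdiff(candidates, current)
    if (!length(remaining)) break
    pnext <- vapply(remaining, function(cn) {
      term_p(data, y, cn, current, covariates)
    }, numeric(1))
    if (!any(!is.na(pnext) & pnext <= entry_p)) break
  }

  retained <- current
  if (length(retained) == 0) {
    return(structure(
      list(retained = character(), entered = entered,
           coefficients = tibble::tibble(), model_auc = NA_real_,
           separation = FALSE, dropped_constant = dropped_constant,
           note = "no candidate satisfied the retention rule"),
      class = "selection_result"))
  }
  ## final model: retained markers + covariates; drop covariates that are
  ## not significant at the stay threshold
  final_fit <- fit_logistic(data, y, unique(c(retained, covariates)))
  keep_cov <- vapply(covariates, function(cn) {
    row <- coef_rows(final_fit$coefficients, cn)
    nrow(row) > 0 && any(!is.na(row$p_value) & row$p_value < stay_p)
  }, logical(1))
  final_fit <- fit_logistic(data, y,
                            unique(c(retained, covariates[keep_cov])))
  lp <- stats::predict(final_fit$fit, type = "link")
  structure(
    list(retained = retained, entered = entered,
         coefficients = final_fit$coefficients,
         model_auc = auc_rank(lp, y, positive = 1),
         separation = final_fit$separation,
         dropped_constant = dropped_constant),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> retained:",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "none",
      sprintf("| AUC %.3f\n", x$model_auc))
  invisible(x)
}
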