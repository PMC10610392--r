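#' Stepwise multiple linear regression with partial R-squared
#'
#' Forward selection with backward elimination: at each step the candidate
#' with the smallest partial-F p-value below `alpha_enter` is added, then any
#' entered predictor whose p-value has risen above `alpha_remove` is dropped.
#' The partial R-squared recorded at entry is the increment in R-squared the
#' predictor contributed when it entered.
#'
#' @param X n x p numeric matrix of candidate predictors (named columns).
#' @param y Response vector.
#' @param alpha_enter,alpha_remove Entry and stay thresholds (defaults
#'   0.05 / 0.10).
#' @param max_steps Safety bound on iterations.
#' @return List: `predictors` (in entry order), `coefficients` tibble
#'   (`term, estimate, se, p`), `steps` tibble (`step, entered, removed,
#'   partial_r2, cumulative_r2`), `r2`, `sigma` (residual standard error),
#'   `fit` (the final `lm`), `intercept_only` flag.
#' @export
stepwise_fit <- function(X, y, alpha_enter = 0.05, alpha_remove = 0.10,
                         max_steps = 100) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    stop_stressmet("`X` must have column names", "stressmet_format_error")
  }
  n <- nrow(X)
  dat <- data.frame(y = y, X, check.names = FALSE)
  in_set <- character(0)
  steps <- list()
  # a perfect fit makes summary() warn and its p-values NaN; those NaNs are
  # treated as "no evidence" (p = 1) so the search just stops
  smry <- function(vars) {
    f <- lm(reformulate(sprintf("`%s`", vars), "y"), data = dat)
    suppressWarnings(summary(f))
  }
  r2_of <- function(vars) {
    if (!length(vars)) return(0)
    smry(vars)$r.squared
  }
  pval_in_model <- function(vars) {
    cf <- smry(vars)$coefficients
    p <- setNames(cf[-1, 4], vars)
    p[is.na(p)] <- 1
    p
  }
  step_i <- 0L
  repeat {
    step_i <- step_i + 1L
    if (step_i > max_steps) break
    cand <- setdiff(colnames(X), in_set)
    entered <- NA_character_; removed <- NA_character_
    if (length(cand) && n > length(in_set) + 2) {
      ps <- vapply(cand, function(v) {
        cf <- smry(c(in_set, v))$coefficients
        p <- if (rownames(cf)[nrow(cf)] == sprintf("`%s`", v) ||
                 rownames(cf)[nrow(cf)] == v) cf[nrow(cf), 4] else NA_real_
        if (is.na(p)) 1 else p
      }, 0)
      if (min(ps) < alpha_enter) {
        entered <- cand[which.min(ps)]
        r2_before <- r2_of(in_set)
        in_set <- c(in_set, entered)
        r2_after <- r2_of(in_set)
        steps[[length(steps) + 1]] <- tibble(
          step = step_i, entered = entered, removed = NA_character_,
          partial_r2 = r2_after - r2_before, cumulative_r2 = r2_after)
      }
    }
    if (length(in_set) > 1) {
      ps <- pval_in_model(in_set)
      worst <- names(ps)[which.max(ps)]
      if (max(ps) > alpha_remove && !identical(worst, entered)) {
        removed <- worst
        in_set <- setdiff(in_set, worst)
        steps[[length(steps) + 1]] <- tibble(
          step = step_i, entered = NA_character_, removed = worst,
          partial_r2 = NA_real_, cumulative_r2 = r2_of(in_set))
      }
    }
    if (is.na(entered) && is.na(removed)) break
  }
  intercept_only <- !length(in_set)
  if (intercept_only) {
    warn("no candidate passed the entry threshold: intercept-only model")
    fit <- lm(y ~ 1, data = dat)
  } else {
    fit <- lm(reformulate(sprintf("`%s`", in_set), "y"), data = dat)
  }
  sm_fit <- suppressWarnings(summary(fit))
  cf <- sm_fit$coefficients
  coefs <- tibble(term = gsub("`", "", rownames(cf)), estimate = cf[, 1],
                  se = cf[, 2], p = cf[, 4])
  list(predictors = in_set, coefficients = coefs,
       steps = if (length(steps)) bind_rows(steps) else
         tibble(step = integer(), entered = character(),
                removed = character(), partial_r2 = numeric(),
                cumulative_r2 = numeric()),
       r2 = sm_fit$r.squared, sigma = sm_fit$sigma,
       fit = fit, intercept_only = intercept_only)
}

#' Coefficients as a named vector (intercept first)
#' @param model A [stepwise_fit()] result, or a named coefficient vector.
#' @keywords internal
coef_vector <- function(model) {
  if (is.list(model) && !is.null(model$coefficients)) {
    setNames(model$coefficients$estimate, model$coefficients$term)
  } else model
}

#' Per-genotype prediction diagnostics of a regression model
#'
#' Applies a fitted (or printed) linear equation to each row and reports the
#' predicted value, prediction error `y - yhat`, relative error
#' `(y - yhat)/y`, and evaluation accuracy `100 * (1 - |relative error|)`,
#' plus the population average accuracy. Rows with `y = 0` have undefined
#' relative error and are flagged.
#'
#' @param model A [stepwise_fit()] result, or a named numeric vector of
#'   coefficients with an `"(Intercept)"` entry (so a published equation can
#'   be evaluated directly).
#' @param X Predictor matrix containing the model's predictor columns.
#' @param y Observed response.
#' @param labels Optional row labels.
#' @param predicted Optional precomputed predictions (e.g. the rounded
#'   values of a published table); when given, `model`/`X` are not used for
#'   prediction.
#' @return Tibble `label, observed, predicted, error, relative_error,
#'   accuracy_pct, undefined`, with attribute `average_accuracy`.
#' @export
predict_report <- function(model, X, y, labels = rownames(X),
                           predicted = NULL) {
  if (is.null(predicted)) {
    b <- coef_vector(model)
    terms <- setdiff(names(b), "(Intercept)")
    X <- as.matrix(X)
    if (!all(terms %in% colnames(X))) {
      stop_stressmet(paste("X lacks predictors:",
                           paste(setdiff(terms, colnames(X)),
                                 collapse = ", ")),
                     "stressmet_format_error")
    }
    yhat <- as.vector(X[, terms, drop = FALSE] %*% b[terms]) +
      if ("(Intercept)" %in% names(b)) b[["(Intercept)"]] else 0
  } else {
    yhat <- predicted
  }
  err <- y - yhat
  undef <- y == 0
  if (any(undef)) warn("rows with observed 0: relative error undefined")
  rel <- ifelse(undef, NA_real_, err / y)
  acc <- 100 * (1 - abs(rel))
  if (is.null(labels)) labels <- as.character(seq_along(y))
  out <- tibble(label = labels, observed = y, predicted = yhat, error = err,
                relative_error = rel, accuracy_pct = acc, undefined = undef)
  attr(out, "average_accuracy") <- mean(acc, na.rm = TRUE)
  out
}
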