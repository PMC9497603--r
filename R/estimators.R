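## Second-step ATE estimators. All take the observed (y, a) and a
## nuisance-prediction triple (ghat, qhat1, qhat0) and return a point
## estimate; asymptotic_ci wraps any of them with an influence-function
## standard error.

#' Nuisance prediction triple
#'
#' Container for the first-step predictions consumed by every estimator:
#' fitted propensities `ghat` (strictly inside (0, 1)) and counterfactual
#' outcome predictions `qhat1`, `qhat0`.
#'
#' @param ghat numeric vector in (0, 1).
#' @param qhat1,qhat0 numeric vectors of the same length.
#' @return an object of class `nuisance_predictions`.
#' @export
nuisance_predictions <- function(ghat, qhat1, qhat0) {
  n <- length(ghat)
  if (length(qhat1) != n || length(qhat0) != n) {
    stop_invalid("ghat, qhat1, qhat0 must have equal lengths", "invalid_input")
  }
  if (any(!is.finite(ghat)) || any(ghat <= 0) || any(ghat >= 1)) {
    stop_invalid("ghat must lie strictly inside (0, 1)", "positivity_violation")
  }
  structure(list(ghat = as.numeric(ghat), qhat1 = as.numeric(qhat1),
                 qhat0 = as.numeric(qhat0)),
            class = "nuisance_predictions")
}

#' @export
print.nuisance_predictions <- function(x, ...) {
  cat("Nuisance predictions for", length(x$ghat), "units\n")
  cat("  ghat range: [", format(min(x$ghat), digits = 4), ",",
      format(max(x$ghat), digits = 4), "]\n")
  cat("  mean qhat1 - qhat0:", format(mean(x$qhat1 - x$qhat0), digits = 5), "\n")
  invisible(x)
}

check_estimator_inputs <- function(y, a, preds) {
  stopifnot(inherits(preds, "nuisance_predictions"))
  if (length(y) != length(a) || length(a) != length(preds$ghat)) {
    stop_invalid("y, a, predictions must have equal lengths", "invalid_input")
  }
  if (!all(a %in% c(0, 1))) {
    stop_invalid("a must be binary 0/1", "invalid_input")
  }
}

## Per-unit contribution vectors; each estimator's point estimate is the mean
## of its contributions, and asymptotic_ci uses their sample SD.
estimator_contributions <- function(method, y, a, preds) {
  g <- preds$ghat; q1 <- preds$qhat1; q0 <- preds$qhat0
  n <- length(y)
  switch(method,
    plug_in = q1 - q0,
    ipw = a * y / g - (1 - a) * y / (1 - g),
    aipw = a * (y - q1) / g - (1 - a) * (y - q0) / (1 - g) + (q1 - q0),
    nipw = {
      if (sum(a) == 0 || sum(a) == n) {
        stop_invalid("both treatment arms must be non-empty", "undefined_estimator")
      }
      w1 <- 1 / g; w0 <- 1 / (1 - g)
      n * a * y * w1 / sum(a * w1) - n * (1 - a) * y * w0 / sum((1 - a) * w0)
    },
    naipw = {
      if (sum(a) == 0 || sum(a) == n) {
        stop_invalid("both treatment arms must be non-empty", "undefined_estimator")
      }
      w1 <- 1 / g; w0 <- 1 / (1 - g)
      n * a * (y - q1) * w1 / sum(a * w1) -
        n * (1 - a) * (y - q0) * w0 / sum((1 - a) * w0) + (q1 - q0)
    },
    stop_invalid(paste("unknown estimator:", method), "invalid_parameter")
  )
}

#' Augmented inverse-probability-weighting (AIPW) ATE estimator
#'
#' `mean( a (y - qhat1) / ghat - (1 - a)(y - qhat0) / (1 - ghat) ) +
#' mean(qhat1 - qhat0)`: the doubly robust combination of the
#' outcome-regression plug-in and the inverse-propensity-weighted residual
#' correction.
#'
#' @param y outcome vector.
#' @param a 0/1 treatment vector.
#' @param preds a [nuisance_predictions()] triple.
#' @return scalar ATE estimate.
#' @export
aipw <- function(y, a, preds) {
  check_estimator_inputs(y, a, preds)
  mean(estimator_contributions("aipw", y, a, preds))
}

#' Normalized (Hajek) AIPW ATE estimator
#'
#' AIPW with the residual-correction weights `w(1) = 1 / ghat` and
#' `w(0) = 1 / (1 - ghat)` normalized within each arm:
#' `sum(a (y - qhat1) w(1)) / sum(a w(1)) -
#' sum((1 - a)(y - qhat0) w(0)) / sum((1 - a) w(0)) + mean(qhat1 - qhat0)`.
#' The normalization bounds the weight terms and stabilizes the estimator
#' when propensities approach 0 or 1 (empirical positivity violations).
#'
#' @inheritParams aipw
#' @return scalar ATE estimate.
#' @export
naipw <- function(y, a, preds) {
  check_estimator_inputs(y, a, preds)
  mean(estimator_contributions("naipw", y, a, preds))
}

#' IPW, normalized IPW, and plug-in comparators
#'
#' `ipw` is the Horvitz-Thompson estimator
#' `mean(a y / ghat - (1 - a) y / (1 - ghat))`; `nipw` is its Hajek
#' normalization; `plug_in` is the outcome-regression-only estimator
#' `mean(qhat1 - qhat0)` (the simple-regression comparator).
#'
#' @inheritParams aipw
#' @return scalar ATE estimate.
#' @export
ipw <- function(y, a, preds) {
  check_estimator_inputs(y, a, preds)
  mean(estimator_contributions("ipw", y, a, preds))
}

#' @rdname ipw
#' @export
nipw <- function(y, a, preds) {
  check_estimator_inputs(y, a, preds)
  mean(estimator_contributions("nipw", y, a, preds))
}

#' @rdname ipw
#' @export
plug_in <- function(preds) {
  stopifnot(inherits(preds, "nuisance_predictions"))
  mean(preds$qhat1 - preds$qhat0)
}

ESTIMATOR_METHODS <- c("aipw", "naipw", "ipw", "nipw", "plug_in")

#' ATE estimate with influence-function confidence interval
#'
#' Computes the chosen estimator and an asymptotic 95% interval: the standard
#' error is the sample standard deviation of the per-unit estimated influence
#' contributions (the terms averaged by the estimator, centered) divided by
#' `sqrt(n)`, and the interval is the point estimate plus/minus 1.96 standard
#' errors.
#'
#' @param method one of `"aipw"`, `"naipw"`, `"ipw"`, `"nipw"`, `"plug_in"`.
#' @inheritParams aipw
#' @return an object of class `ate_estimate` with fields `method`, `point`,
#'   `stderr`, `ci_lower`, `ci_upper`, `n`.
#' @export
asymptotic_ci <- function(method, y, a, preds) {
  method <- match.arg(method, ESTIMATOR_METHODS)
  check_estimator_inputs(y, a, preds)
  n <- length(y)
  if (n < 2) stop_invalid("need at least 2 units", "undefined_estimator")
  d <- estimator_contributions(method, y, a, preds)
  point <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  structure(list(method = method, point = point, stderr = se,
                 ci_lower = point - 1.96 * se, ci_upper = point + 1.96 * se,
                 n = n),
            class = "ate_estimate")
}

#' @export
print.ate_estimate <- function(x, ...) {
  cat(sprintf("ATE (%s): %.4f  SE %.4f  95%% CI [%.4f, %.4f]  n = %d\n",
              x$method, x$point, x$stderr, x$ci_lower, x$ci_upper, x$n))
  invisible(x)
}

#' All estimators at once
#'
#' @inheritParams aipw
#' @return named numeric vector of the five point estimates.
#' @export
estimate_all <- function(y, a, preds) {
  check_estimator_inputs(y, a, preds)
  vapply(ESTIMATOR_METHODS, function(m) {
    mean(estimator_contributions(m, y, a, preds))
  }, numeric(1))
}
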