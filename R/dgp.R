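## Synthetic data-generating process: AR(1)-correlated Gaussian covariates in
## four labeled roles (confounder, instrument, outcome predictor, irrelevant),
## pairwise nonlinear features feeding a logistic treatment model and a
## linear-plus-nonlinear continuous outcome with a constant additive effect.

ROLE_LEVELS <- c("confounder", "iv", "y_predictor", "irrelevant")

#' Scenario configuration for the simulation DGP
#'
#' Full parameterization of one simulation scenario: sample size, covariate
#' dimension, the four role block sizes, the autoregressive correlation of the
#' covariates, the true additive treatment effect, the coefficient ranges for
#' confounder/outcome-predictor effects and instrument effects, the fraction
#' of each block entering pairwise nonlinear transformations, and the outcome
#' noise scale.
#'
#' @param n number of subjects (>= 2).
#' @param p number of covariates; must equal `sum(block_sizes)`.
#' @param block_sizes integer vector of length 4: counts of confounders,
#'   instruments, outcome predictors, and irrelevant covariates.
#' @param rho autoregressive correlation in \[0, 1): covariate covariance
#'   entry (k, j) is `rho^|j - k|`.
#' @param beta true additive treatment effect on the outcome.
#' @param intercept outcome intercept.
#' @param conf_range length-2 range (r1, r2) for the uniform draws of the
#'   confounder-to-treatment, confounder-to-outcome, and outcome-predictor
#'   coefficients.
#' @param iv_range length-2 range (r3, r4) for the instrument-to-treatment
#'   coefficient draws.
#' @param nonlinear_fraction fraction of each block's columns selected into
#'   pairwise nonlinear transformations.
#' @param noise_sd standard deviation of the Gaussian outcome noise.
#' @param seed integer seed controlling every random draw of the scenario.
#' @return an object of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(n = 750, p = 32, seed = 1)
#' @export
scenario_config <- function(n = 750, p = 32,
                            block_sizes = rep(p / 4, 4),
                            rho = 0.5, beta = 1, intercept = 3,
                            conf_range = c(0.1, 0.1),
                            iv_range = c(0.1, 0.1),
                            nonlinear_fraction = 0.3,
                            noise_sd = 1, seed = 1L) {
  block_sizes <- as.integer(block_sizes)
  if (!(length(n) == 1 && n >= 2)) {
    stop_invalid("n must be a single value >= 2", "invalid_parameter")
  }
  if (length(block_sizes) != 4 || any(block_sizes < 0)) {
    stop_invalid("block_sizes must be 4 nonnegative counts", "invalid_parameter")
  }
  if (sum(block_sizes) != p) {
    stop_invalid("block_sizes must sum to p", "invalid_parameter")
  }
  if (!(rho >= 0 && rho < 1)) {
    stop_invalid("rho must lie in [0, 1)", "invalid_parameter")
  }
  if (conf_range[1] > conf_range[2] || iv_range[1] > iv_range[2]) {
    stop_invalid("coefficient ranges must satisfy low <= high", "invalid_parameter")
  }
  if (nonlinear_fraction < 0 || nonlinear_fraction > 1) {
    stop_invalid("nonlinear_fraction must lie in [0, 1]", "invalid_parameter")
  }
  structure(list(
    n = as.integer(n), p = as.integer(p), block_sizes = block_sizes,
    rho = rho, beta = beta, intercept = intercept,
    conf_range = conf_range, iv_range = iv_range,
    nonlinear_fraction = nonlinear_fraction,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Simulation scenario: n =", x$n, ", p =", x$p, "\n")
  cat("  blocks (conf/iv/ypred/irr):", paste(x$block_sizes, collapse = "/"), "\n")
  cat("  rho =", x$rho, ", beta =", x$beta, ", intercept =", x$intercept, "\n")
  cat("  conf/ypred coef range:", paste(x$conf_range, collapse = ".."),
      " iv coef range:", paste(x$iv_range, collapse = ".."), "\n")
  cat("  nonlinear fraction:", x$nonlinear_fraction,
      " noise sd:", x$noise_sd, " seed:", x$seed, "\n")
  invisible(x)
}

#' Draw autoregressive-correlated Gaussian covariates
#'
#' Rows are i.i.d. draws from a zero-mean multivariate normal with covariance
#' `Sigma[k, j] = rho^|j - k|` (AR(1) structure, unit variances).
#'
#' @param n number of rows (>= 2).
#' @param p number of columns (>= 1).
#' @param rho autoregressive correlation in \[0, 1).
#' @param seed integer seed.
#' @return an `n x p` numeric matrix.
#' @export
draw_covariates <- function(n, p, rho, seed = NULL) {
  if (!(rho >= 0 && rho < 1)) {
    stop_invalid("rho must lie in [0, 1)", "invalid_parameter")
  }
  stopifnot(n >= 2, p >= 1)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * p), n, p)
    if (rho == 0 || p == 1) return(z)
    sigma <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
    z %*% chol(sigma)
  })
}

#' Piecewise-constant step functions of the nonlinear catalogue
#'
#' `step_g` and `step_h` are the two step-function pairs used by the fifth
#' pairwise transformation family. Variant 1 is a sum of indicator terms,
#' `g(x) = -2 I(x <= -1) - I(-1 <= x <= 0) + I(0 <= x <= 2) + 3 I(x >= 2)` and
#' `h(x) = -5 I(x <= 0) - 2 I(0 <= x <= 1) + 3 I(x >= 1)`; at breakpoints where
#' two indicators are simultaneously true their contributions add, which keeps
#' the functions deterministic everywhere. Variant 2 is the simpler pair
#' `g(x) = I(x >= 0)`, `h(x) = I(x >= 1)`.
#'
#' @param x numeric vector.
#' @param variant 1 or 2.
#' @return numeric vector of the same length.
#' @export
step_g <- function(x, variant = 1) {
  variant <- match.arg(as.character(variant), c("1", "2"))
  if (variant == "1") {
    -2 * (x <= -1) - (x >= -1 & x <= 0) + (x >= 0 & x <= 2) + 3 * (x >= 2)
  } else {
    as.numeric(x >= 0)
  }
}

#' @rdname step_g
#' @export
step_h <- function(x, variant = 1) {
  variant <- match.arg(as.character(variant), c("1", "2"))
  if (variant == "1") {
    -5 * (x <= 0) - 2 * (x >= 0 & x <= 1) + 3 * (x >= 1)
  } else {
    as.numeric(x >= 1)
  }
}

#' Catalogue of pairwise nonlinear transformation families
#'
#' The ordered catalogue of the five transformation families applied to
#' selected covariate pairs:
#' 1. `exp(x1 * x2 / 2)`
#' 2. `x1 / (1 + exp(x2))`
#' 3. `(x1 * x2 / 10 + 2)^3`
#' 4. `(x1 + x2 + 3)^2`
#' 5. `g(x1) * h(x2)` with the step functions [step_g()] and [step_h()]
#'    (variant chosen per use and recorded).
#'
#' The order is fixed so that an indexed selection is reproducible.
#'
#' @return a list of five functions `f(x1, x2, variant)`; only the fifth uses
#'   `variant`.
#' @export
nonlinear_library <- function() {
  list(
    function(x1, x2, variant = 1) exp(x1 * x2 / 2),
    function(x1, x2, variant = 1) x1 / (1 + exp(x2)),
    function(x1, x2, variant = 1) (x1 * x2 / 10 + 2)^3,
    function(x1, x2, variant = 1) (x1 + x2 + 3)^2,
    function(x1, x2, variant = 1) step_g(x1, variant) * step_h(x2, variant)
  )
}

#' Build pairwise nonlinear features from a covariate block
#'
#' Selects `ceiling(fraction * ncol(block))` columns without replacement,
#' partitions them into consecutive disjoint pairs (an odd leftover column is
#' paired with the first selected column), and maps each pair through a
#' catalogue entry drawn uniformly from [nonlinear_library()]. When the fifth
#' (step-function) family is drawn, its variant is also drawn and recorded.
#'
#' @param block `n x m` numeric matrix.
#' @param fraction fraction of columns to select, in \[0, 1\].
#' @param seed integer seed.
#' @return a list with `features` (an `n x q` matrix, `q` = number of pairs)
#'   and `record` (a data.frame with columns `col1`, `col2`, `entry`,
#'   `variant` describing each feature).
#' @export
make_pair_features <- function(block, fraction, seed = NULL) {
  stopifnot(is.matrix(block))
  m <- ncol(block)
  n <- nrow(block)
  empty <- list(features = matrix(numeric(0), n, 0),
                record = data.frame(col1 = integer(0), col2 = integer(0),
                                    entry = integer(0), variant = integer(0)))
  if (fraction == 0) return(empty)
  if (m < 2) {
    stop_invalid("block needs at least 2 columns when fraction > 0",
                 "degenerate_block")
  }
  lib <- nonlinear_library()
  with_seed(seed, {
    n_sel <- ceiling(fraction * m)
    sel <- sample.int(m, n_sel)
    first <- seq(1, n_sel, by = 2)
    q <- length(first)
    feats <- matrix(NA_real_, n, q)
    rec <- data.frame(col1 = integer(q), col2 = integer(q),
                      entry = integer(q), variant = integer(q))
    for (j in seq_len(q)) {
      i <- first[j]
      c1 <- sel[i]
      c2 <- if (i + 1 <= n_sel) sel[i + 1] else sel[1]
      entry <- sample.int(5, 1)
      variant <- if (entry == 5) sample.int(2, 1) else NA_integer_
      feats[, j] <- lib[[entry]](block[, c1], block[, c2],
                                 if (is.na(variant)) 1 else variant)
      rec$col1[j] <- c1; rec$col2[j] <- c2
      rec$entry[j] <- entry; rec$variant[j] <- variant
    }
    list(features = feats, record = rec)
  })
}

#' Draw uniform coefficients
#'
#' @param low,high range bounds, `low <= high`.
#' @param count number of draws.
#' @param seed integer seed.
#' @return numeric vector of independent Uniform(low, high) draws.
#' @export
sample_coefficients <- function(low, high, count, seed = NULL) {
  if (low > high) stop_invalid("low must be <= high", "invalid_parameter")
  stopifnot(count >= 0)
  if (count == 0) return(numeric(0))
  with_seed(seed, stats::runif(count, low, high))
}

#' Draw treatment assignments from a logistic model
#'
#' Propensities are the inverse logit of the linear predictor `eta`; each
#' treatment indicator is an independent Bernoulli draw at its propensity.
#' Because the logistic function saturates to exactly 0 or 1 in double
#' precision for |eta| beyond ~37, the returned propensities are clamped to
#' \[1e-12, 1 - 1e-12\] so they stay strictly inside (0, 1) as every
#' downstream weight computation requires.
#'
#' @param eta numeric linear-predictor vector (finite).
#' @param seed integer seed.
#' @return list with `a` (0/1 integer vector) and `propensity`.
#' @export
sample_treatment <- function(eta, seed = NULL) {
  if (any(!is.finite(eta))) {
    stop_invalid("eta must be finite", "invalid_input")
  }
  g <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  a <- with_seed(seed, stats::rbinom(length(eta), 1L, g))
  list(a = a, propensity = g)
}

#' Assemble the outcome and both potential outcomes
#'
#' `Y0 = intercept + conf_term + ypred_term + noise`, `Y1 = Y0 + beta`, and
#' the observed `Y = A * Y1 + (1 - A) * Y0`. The treatment enters only through
#' the additive constant `beta`, so `Y1 - Y0 = beta` for every unit.
#'
#' @param a 0/1 treatment vector.
#' @param conf_term confounder contribution to the outcome (length n).
#' @param ypred_term outcome-predictor contribution (length n).
#' @param beta additive treatment effect.
#' @param intercept outcome intercept.
#' @param noise noise vector (length n).
#' @return list with `y`, `y0`, `y1`, and `mu0` (the noise-free mean of `y0`,
#'   i.e. the true `E[Y | A = 0, W]`).
#' @export
generate_outcome <- function(a, conf_term, ypred_term, beta, intercept, noise) {
  n <- length(a)
  if (length(conf_term) != n || length(ypred_term) != n || length(noise) != n) {
    stop_invalid("all vectors must have the same length", "invalid_input")
  }
  mu0 <- intercept + conf_term + ypred_term
  y0 <- mu0 + noise
  y1 <- y0 + beta
  list(y = a * y1 + (1 - a) * y0, y0 = y0, y1 = y1, mu0 = mu0)
}

#' Simulate one dataset from a scenario configuration
#'
#' Draws the covariate matrix, labels the four role blocks, builds four
#' independent pairwise-nonlinear feature sets (treatment-side transformations
#' of the confounders and instruments; outcome-side transformations of the
#' confounders and outcome predictors — the treatment and outcome sides select
#' and transform the confounders independently), draws uniform coefficients,
#' forms the treatment linear predictor (no intercept), assigns treatment, and
#' generates the outcome with its potential outcomes. All ground truth
#' (potential outcomes, true propensities, coefficients, transformation
#' records) is retained for evaluation. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [scenario_config()].
#' @return an object of class `sim_dataset` with fields `w`, `roles`, `a`,
#'   `y`, `y0`, `y1`, `mu0` (true `E[Y | A = 0, W]`), `g_true`, `eta`,
#'   `coefficients`, `transformations`, `config`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n; p <- config$p; bs <- config$block_sizes
  seed <- config$seed
  w <- draw_covariates(n, p, config$rho, derive_seed(seed, "covariates"))
  colnames(w) <- paste0("W_", seq_len(p))
  roles <- rep(ROLE_LEVELS, times = bs)
  idx <- split(seq_len(p), factor(roles, levels = ROLE_LEVELS))
  block <- function(role) w[, idx[[role]], drop = FALSE]

  frac <- config$nonlinear_fraction
  fa <- make_pair_features(block("confounder"), frac, derive_seed(seed, "fa"))
  ga <- make_pair_features(block("iv"), frac, derive_seed(seed, "ga"))
  fy <- make_pair_features(block("confounder"), frac, derive_seed(seed, "fy"))
  gy <- make_pair_features(block("y_predictor"), frac, derive_seed(seed, "gy"))

  coef_draw <- function(range, count, tag) {
    sample_coefficients(range[1], range[2], count, derive_seed(seed, tag))
  }
  gamma_c <- coef_draw(config$conf_range, ncol(fa$features), "gamma_c")
  gamma_iv <- coef_draw(config$iv_range, ncol(ga$features), "gamma_iv")
  gamma_c2 <- coef_draw(config$conf_range, ncol(fy$features), "gamma_c2")
  gamma_y <- coef_draw(config$conf_range, ncol(gy$features), "gamma_y")

  lin <- function(feats, gam) {
    if (length(gam) == 0) rep(0, n) else drop(feats %*% gam)
  }
  eta <- lin(fa$features, gamma_c) + lin(ga$features, gamma_iv)
  trt <- sample_treatment(eta, derive_seed(seed, "treatment"))
  noise <- with_seed(derive_seed(seed, "noise"),
                     stats::rnorm(n, 0, config$noise_sd))
  out <- generate_outcome(trt$a, lin(fy$features, gamma_c2),
                          lin(gy$features, gamma_y),
                          config$beta, config$intercept, noise)

  structure(list(
    w = w, roles = roles, a = trt$a, y = out$y, y0 = out$y0, y1 = out$y1,
    mu0 = out$mu0, g_true = trt$propensity, eta = eta,
    coefficients = list(gamma_c = gamma_c, gamma_iv = gamma_iv,
                        gamma_c2 = gamma_c2, gamma_y = gamma_y),
    transformations = list(fa = fa$record, ga = ga$record,
                           fy = fy$record, gy = gy$record),
    config = config
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated causal dataset: n =", nrow(x$w), ", p =", ncol(x$w), "\n")
  cat("  roles:", paste(sprintf("%s=%d", ROLE_LEVELS,
                                tabulate(factor(x$roles, ROLE_LEVELS), 4)),
                        collapse = ", "), "\n")
  cat("  treated fraction:", round(mean(x$a), 3),
      " true effect (beta):", x$config$beta, "\n")
  cat("  propensity range: [", round(min(x$g_true), 4), ",",
      round(max(x$g_true), 4), "]\n")
  invisible(x)
}

#' The eight-scenario grid of the simulation study
#'
#' Crosses two data sizes (n = 750 with p = 32; n = 7500 with p = 300, equal
#' role blocks of 8 and 75) with weak/strong confounder coefficient ranges
#' ((0.1, 0.1) vs (0.1, 1)) and weak/strong instrument ranges.
#'
#' @param seed base seed; scenario `i` gets a derived child seed.
#' @return a named list of eight [scenario_config()] objects.
#' @export
scenario_grid <- function(seed = 1L) {
  sizes <- list(small = c(n = 750, p = 32), large = c(n = 7500, p = 300))
  strengths <- list(weak = c(0.1, 0.1), strong = c(0.1, 1))
  out <- list()
  for (sz in names(sizes)) for (cs in names(strengths)) for (is in names(strengths)) {
    id <- paste(sz, paste0("conf_", cs), paste0("iv_", is), sep = ".")
    out[[id]] <- scenario_config(
      n = sizes[[sz]]["n"], p = sizes[[sz]]["p"],
      block_sizes = rep(sizes[[sz]]["p"] / 4, 4),
      conf_range = strengths[[cs]], iv_range = strengths[[is]],
      seed = derive_seed(seed, id)
    )
  }
  out
}
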