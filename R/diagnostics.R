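## Prediction-quality and covariate-capture diagnostics: R^2 for the outcome
## model, AUC / Somers' D for the treatment model, the geo compromise
## statistic, distance correlation, and the top-k role capture counts.

#' Somers' D from AUC
#'
#' The rank correlation `D = 2 (AUC - 0.5)` for a binary classifier.
#'
#' @param auc a value in \[0, 1\].
#' @return a value in \[-1, 1\].
#' @export
somers_d <- function(auc) {
  if (any(auc < 0 | auc > 1)) {
    stop_invalid("auc must lie in [0, 1]", "invalid_parameter")
  }
  2 * (auc - 0.5)
}

#' The geo model-selection statistic
#'
#' The cube root of `R^2 * D * (1 - D)` with `D = 2 (AUC - 0.5)`: a
#' geometric-type compromise that rewards a good outcome fit together with a
#' moderate — not perfect — treatment discrimination (for fixed R^2 it is
#' maximized at AUC = 0.75). A negative R^2 (possible out of sample) and a
#' negative product (AUC below 0.5) are clamped to 0 so the cube root stays
#' real and the statistic nonnegative.
#'
#' @param r2 outcome-model R^2 (any real value <= 1).
#' @param auc treatment-model AUC in \[0, 1\].
#' @return nonnegative scalar, at most `(0.25)^(1/3)`.
#' @export
geo_stat <- function(r2, auc) {
  d <- somers_d(auc)
  pmax(pmax(r2, 0) * d * (1 - d), 0)^(1 / 3)
}

#' Coefficient of determination
#'
#' `1 - SSE / SST` about the mean of `y`.
#'
#' @param yhat predictions.
#' @param y observations (non-constant).
#' @return a value <= 1 (can be negative for poor predictions).
#' @export
r2_score <- function(yhat, y) {
  stopifnot(length(yhat) == length(y))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop_invalid("y is constant; R^2 undefined", "undefined_r2")
  1 - sum((y - yhat)^2) / sst
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen positive outranks a
#' randomly chosen negative, ties counted one half (midrank formula).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels with both classes present.
#' @return a value in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_invalid("both classes must be present", "undefined_auc")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Distance correlation (classical V-statistic)
#'
#' The 2007-style biased estimator: pairwise absolute-difference matrices of
#' `u` and `v` are double-centered (row means, column means, and grand mean
#' removed); `dCov^2` is the mean of their elementwise product, `dVar^2` the
#' mean of each centered matrix squared, and
#' `dCor = dCov / sqrt(dVar_u * dVar_v)`. Returns 0 when either `dVar` is 0
#' (a constant input). Zero at the population level iff the variables are
#' independent; equals 1 under nondegenerate linear maps.
#'
#' @param u,v numeric vectors of equal length `n >= 2`.
#' @return a value in \[0, 1\].
#' @export
distance_correlation <- function(u, v) {
  n <- length(u)
  stopifnot(length(v) == n, n >= 2)
  center <- function(x) {
    d <- abs(outer(x, x, "-"))
    d - rowMeans(d) - rep(colMeans(d), each = n) + mean(d)
  }
  au <- center(u); av <- center(v)
  dvu <- mean(au * au); dvv <- mean(av * av)
  if (dvu == 0 || dvv == 0) return(0)
  dcov2 <- max(mean(au * av), 0)
  sqrt(dcov2 / sqrt(dvu * dvv))
}

#' Top-k covariate capture counts
#'
#' For each model's in-sample prediction vector (outcome `yhat`, treatment
#' `ghat`), computes the distance correlation against every covariate column,
#' ranks columns by descending association (ties broken by lower column
#' index), keeps the top `k`, and counts how many of each covariate role land
#' in the top set — the capture diagnostic showing which covariate types a
#' model has learned from.
#'
#' @param w `n x p` covariate matrix.
#' @param roles length-p role labels over `confounder`, `iv`, `y_predictor`,
#'   `irrelevant`.
#' @param yhat,ghat in-sample prediction vectors.
#' @param k number of top inputs to count (default 15; capped at p with a
#'   warning).
#' @param subsample_n optional row-subsample size for the distance
#'   correlations (seeded), to bound the O(n^2) cost at large n; default uses
#'   all rows.
#' @param seed seed for the optional subsample.
#' @return an object of class `capture_counts`: a `2 x 4` count matrix
#'   (models x roles) plus the per-column association tables.
#' @export
capture_counts <- function(w, roles, yhat, ghat, k = 15,
                           subsample_n = NULL, seed = 1L) {
  p <- ncol(w)
  stopifnot(length(roles) == p, nrow(w) == length(yhat),
            length(yhat) == length(ghat))
  if (k > p) {
    warning("k exceeds the number of covariates; capped at p")
    k <- p
  }
  rows <- seq_len(nrow(w))
  if (!is.null(subsample_n) && subsample_n < nrow(w)) {
    rows <- with_seed(seed, sort(sample.int(nrow(w), subsample_n)))
  }
  assoc <- function(pred) {
    vapply(seq_len(p), function(j) {
      distance_correlation(w[rows, j], pred[rows])
    }, numeric(1))
  }
  count_top <- function(dcors) {
    ord <- order(-dcors, seq_len(p))  # ties -> lower column index first
    top <- ord[seq_len(k)]
    tabulate(factor(roles[top], levels = ROLE_LEVELS), 4)
  }
  d_y <- assoc(yhat); d_g <- assoc(ghat)
  counts <- rbind(outcome = count_top(d_y), treatment = count_top(d_g))
  colnames(counts) <- ROLE_LEVELS
  structure(list(counts = counts, k = as.integer(k),
                 assoc = data.frame(column = seq_len(p), role = roles,
                                    dcor_outcome = d_y, dcor_treatment = d_g)),
            class = "capture_counts")
}

#' @export
print.capture_counts <- function(x, ...) {
  cat("Covariate roles captured among top", x$k, "inputs:\n")
  print(x$counts)
  invisible(x)
}

#' Prediction metrics of a fitted nuisance model
#'
#' @param yhat,y outcome predictions and observations.
#' @param ghat,a propensity predictions and treatment labels.
#' @return an object of class `prediction_metrics` with `r2`, `auc`,
#'   `somers_d`, `geo`.
#' @export
prediction_metrics <- function(yhat, y, ghat, a) {
  r2 <- r2_score(yhat, y)
  auc <- auc_score(ghat, a)
  structure(list(r2 = r2, auc = auc, somers_d = somers_d(auc),
                 geo = geo_stat(r2, auc)),
            class = "prediction_metrics")
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.4f  AUC = %.4f  Somers' D = %.4f  geo = %.4f\n",
              x$r2, x$auc, x$somers_d, x$geo))
  invisible(x)
}
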