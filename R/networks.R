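## jNN / dNN architectures. Both families share the same building block: a
## ReLU multilayer-perceptron trunk whose last hidden layer H feeds linear
## output heads, plus linear skip connections from the raw covariates to each
## head and a scalar linear term carrying the treatment into the outcome head.
## The treatment indicator never enters the trunk or the treatment head, so
## fitted propensities cannot condition on A and the counterfactual contrast
## qhat1 - qhat0 is the network's own treatment coefficient everywhere.

#' Architecture specification
#'
#' @param widths integer vector of hidden-layer sizes (all >= 1).
#' @param family `"joint"` (shared trunk, two heads) or `"double"` (two
#'   disjoint networks).
#' @return an object of class `architecture_spec`.
#' @export
architecture_spec <- function(widths, family = c("joint", "double")) {
  family <- match.arg(family)
  widths <- as.integer(widths)
  if (length(widths) < 1 || any(widths < 1)) {
    stop_invalid("widths must be a nonempty vector of sizes >= 1",
                 "invalid_parameter")
  }
  structure(list(widths = widths, family = family),
            class = "architecture_spec")
}

## He-style fan-in-scaled symmetric uniform initialization for ReLU layers.
init_matrix <- function(n_in, n_out) {
  limit <- sqrt(6 / n_in)
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

init_trunk <- function(p, widths) {
  dims <- c(p, widths)
  lapply(seq_along(widths), function(l) {
    list(w = init_matrix(dims[l], dims[l + 1]), b = numeric(widths[l]))
  })
}

## One half of an architecture: trunk + the heads it owns.
## heads is a subset of c("y", "a").
init_core <- function(p, widths, heads) {
  lh <- widths[length(widths)]
  core <- list(trunk = init_trunk(p, widths), heads = heads)
  if ("y" %in% heads) {
    core$gamma_y <- drop(init_matrix(lh, 1))
    core$alpha <- numeric(p)
    core$alpha0 <- 0
    core$beta_net <- 0
  }
  if ("a" %in% heads) {
    core$gamma_a <- drop(init_matrix(lh, 1))
    core$gamma <- numeric(p)
    core$gamma0 <- 0
  }
  core
}

#' Create a joint (jNN) network
#'
#' Shared ReLU trunk with an outcome head and a treatment head:
#' `E[Y | A, W] = alpha0 + beta_net * A + W alpha + H Gamma_Y` and
#' `E[A | W] = logistic(gamma0 + W gamma + H Gamma_A)`, where `H` is the last
#' hidden layer of the trunk evaluated at `W`. Trunk weights use seeded
#' fan-in-scaled symmetric-uniform initialization; intercepts, skip weights
#' and the treatment coefficient start at zero.
#'
#' @param p input dimension (number of covariates).
#' @param widths hidden-layer sizes.
#' @param seed integer seed for the initialization.
#' @return an object of class `joint_network`.
#' @export
joint_network <- function(p, widths, seed = NULL) {
  spec <- architecture_spec(widths, "joint")
  core <- with_seed(seed, init_core(p, spec$widths, c("y", "a")))
  structure(list(family = "joint", p = as.integer(p), widths = spec$widths,
                 core = core, standardize = NULL),
            class = c("joint_network", "nn_model"))
}

#' Create a double (dNN) network pair
#'
#' Two fully disjoint networks: an outcome network (trunk, outcome head,
#' covariate skip, treatment coefficient) and a treatment network (its own
#' trunk, treatment head, covariate skip). No parameter is shared. Both
#' trunks use the same widths.
#'
#' @inheritParams joint_network
#' @return an object of class `double_network`.
#' @export
double_network <- function(p, widths, seed = NULL) {
  spec <- architecture_spec(widths, "double")
  cores <- with_seed(seed, list(
    outcome = init_core(p, spec$widths, "y"),
    treatment = init_core(p, spec$widths, "a")
  ))
  structure(list(family = "double", p = as.integer(p), widths = spec$widths,
                 outcome = cores$outcome, treatment = cores$treatment,
                 standardize = NULL),
            class = c("double_network", "nn_model"))
}

#' @export
print.nn_model <- function(x, ...) {
  cat(if (x$family == "joint") "Joint" else "Double",
      "neural network: p =", x$p,
      ", hidden widths =", paste(x$widths, collapse = "-"), "\n")
  cat("  trunk parameters under L1:",
      count_trunk_params(x$p, x$widths, x$family), "\n")
  if (!is.null(x$standardize)) cat("  fitted (inputs standardized)\n")
  invisible(x)
}

apply_standardize <- function(net, w) {
  s <- net$standardize
  if (is.null(s)) return(w)
  sweep(sweep(w, 2, s$center, "-"), 2, s$scale, "/")
}

## Forward pass through one core. Returns yhat/ghat (as owned) and the
## activations needed for backpropagation.
forward_core <- function(core, w, a = NULL, keep = FALSE) {
  z <- w
  zs <- if (keep) vector("list", length(core$trunk)) else NULL
  ss <- zs
  for (l in seq_along(core$trunk)) {
    s <- sweep(z %*% core$trunk[[l]]$w, 2, core$trunk[[l]]$b, "+")
    z <- pmax(s, 0)
    if (keep) { ss[[l]] <- s; zs[[l]] <- z }
  }
  out <- list(h = z)
  if ("y" %in% core$heads) {
    out$yhat <- core$alpha0 + core$beta_net * a +
      drop(w %*% core$alpha) + drop(z %*% core$gamma_y)
  }
  if ("a" %in% core$heads) {
    logit <- core$gamma0 + drop(w %*% core$gamma) + drop(z %*% core$gamma_a)
    out$logit <- logit
    out$ghat <- pmin(pmax(stats::plogis(logit), 1e-12), 1 - 1e-12)
  }
  if (keep) { out$ss <- ss; out$zs <- zs }
  out
}

#' Forward evaluation of a joint network
#'
#' @param net a [joint_network()].
#' @param w `n x p` covariate matrix (raw scale; a fitted network applies its
#'   stored training standardization internally).
#' @param a length-n 0/1 treatment vector.
#' @return list with `yhat` (outcome predictions) and `ghat` (propensities,
#'   strictly inside (0, 1)).
#' @export
forward_joint <- function(net, w, a) {
  stopifnot(inherits(net, "joint_network"))
  if (ncol(w) != net$p) {
    stop_invalid("covariate matrix width does not match network input size",
                 "invalid_input")
  }
  if (length(a) != nrow(w)) {
    stop_invalid("treatment vector length does not match rows of w",
                 "invalid_input")
  }
  f <- forward_core(net$core, apply_standardize(net, w), a)
  list(yhat = f$yhat, ghat = f$ghat)
}

#' Forward evaluation of a double network pair
#'
#' @param net a [double_network()].
#' @inheritParams forward_joint
#' @return list with `yhat` and `ghat`; the treatment network never sees `a`.
#' @export
forward_double <- function(net, w, a) {
  stopifnot(inherits(net, "double_network"))
  if (ncol(w) != net$p) {
    stop_invalid("covariate matrix width does not match network input size",
                 "invalid_input")
  }
  if (length(a) != nrow(w)) {
    stop_invalid("treatment vector length does not match rows of w",
                 "invalid_input")
  }
  ws <- apply_standardize(net, w)
  list(yhat = forward_core(net$outcome, ws, a)$yhat,
       ghat = forward_core(net$treatment, ws)$ghat)
}

forward_model <- function(net, w, a) {
  if (net$family == "joint") forward_joint(net, w, a) else forward_double(net, w, a)
}

#' Counterfactual outcome predictions
#'
#' Evaluates the outcome model with the treatment input forced to 1 and to 0.
#' Because the treatment enters the outcome head only through the linear
#' coefficient `beta_net`, `qhat1 - qhat0 = beta_net` for every unit in both
#' families.
#'
#' @param net a fitted or initialized [joint_network()] or
#'   [double_network()].
#' @param w covariate matrix.
#' @return list with `qhat1` and `qhat0`.
#' @export
predict_counterfactuals <- function(net, w) {
  n <- nrow(w)
  f1 <- forward_model(net, w, rep(1, n))
  f0 <- forward_model(net, w, rep(0, n))
  list(qhat1 = f1$yhat, qhat0 = f0$yhat)
}

#' Number of trunk-and-head parameters under the global L1 penalty
#'
#' For the joint family the count is
#' `(p + 1) l1 + (l1 + 1) l2 + ... + (l_{h-1} + 1) l_h + (l_h + 1) * 2`
#' (per-layer intercepts included; the final factor 2 covers the two heads).
#' For the double family each network has one head (final factor 1) and the
#' total is twice the single-network count, both trunks sharing the same
#' widths.
#'
#' @param p input dimension.
#' @param widths hidden-layer sizes.
#' @param family `"joint"` or `"double"`.
#' @return integer parameter count.
#' @examples
#' count_trunk_params(32, c(32, 32, 32), "joint")  # 3234
#' @export
count_trunk_params <- function(p, widths, family = c("joint", "double")) {
  family <- match.arg(family)
  dims <- c(p, widths)
  trunk <- sum((dims[-length(dims)] + 1) * widths)
  lh <- widths[length(widths)]
  if (family == "joint") trunk + (lh + 1) * 2 else 2L * (trunk + (lh + 1))
}

## Flatten the L1 penalty set P of one core into a list of tensors: trunk
## weights + per-layer intercepts + head weights + output-layer intercepts
## (the count formula's (lh + 1) per head includes the head's intercept).
## targeted = TRUE restricts to Gamma_A + first layer instead.
core_penalty_params <- function(core, targeted = FALSE) {
  out <- list()
  if (targeted) {
    if ("a" %in% core$heads) out$gamma_a <- core$gamma_a
    out$w1 <- core$trunk[[1]]$w
    out$b1 <- core$trunk[[1]]$b
    return(out)
  }
  for (l in seq_along(core$trunk)) {
    out[[paste0("w", l)]] <- core$trunk[[l]]$w
    out[[paste0("b", l)]] <- core$trunk[[l]]$b
  }
  if ("y" %in% core$heads) {
    out$gamma_y <- core$gamma_y
    out$alpha0 <- core$alpha0
  }
  if ("a" %in% core$heads) {
    out$gamma_a <- core$gamma_a
    out$gamma0 <- core$gamma0
  }
  out
}

model_cores <- function(net) {
  if (net$family == "joint") list(joint = net$core)
  else list(outcome = net$outcome, treatment = net$treatment)
}
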