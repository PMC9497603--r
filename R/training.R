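## Multi-task training of the jNN / dNN nuisance models: squared-error loss
## for the continuous outcome, cross-entropy for the binary treatment, a
## global L1 penalty on the trunk-and-heads parameter set P, and a targeted
## L1 penalty on the treatment head and first hidden layer. Gradients are
## computed by hand-written backpropagation with the L1 subgradient (0 at 0);
## optimization is mini-batch Adam with seeded shuffling.

#' Loss configuration
#'
#' @param a weight of the outcome squared-error term.
#' @param b weight of the treatment cross-entropy term.
#' @param cl1 global L1 constant applied to the trunk-and-heads set P.
#' @param cl1tg targeted L1 constant applied to the treatment head and the
#'   first hidden layer. In the double family it acts only on the treatment
#'   network; in the joint family the shared first layer is included.
#' @param cl1_y,cl1_a double-family overrides of the global L1 constant for
#'   the outcome and treatment networks (default: both equal `cl1`).
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(a = 1, b = 1, cl1 = 0, cl1tg = 0,
                        cl1_y = cl1, cl1_a = cl1) {
  if (a < 0 || b < 0 || (a == 0 && b == 0)) {
    stop_invalid("a, b must be >= 0 and not both 0", "invalid_parameter")
  }
  if (cl1 < 0 || cl1tg < 0 || cl1_y < 0 || cl1_a < 0) {
    stop_invalid("L1 constants must be >= 0", "invalid_parameter")
  }
  structure(list(a = a, b = b, cl1 = cl1, cl1tg = cl1tg,
                 cl1_y = cl1_y, cl1_a = cl1_a),
            class = "loss_config")
}

#' Optimizer configuration
#'
#' Mini-batch Adam with the first-moment decay exposed as the momentum knob.
#' Defaults: learning rate 0.01, first-moment decay 0.95 (second-moment decay
#' 0.999, epsilon 1e-8), 200 epochs, batch size `3 * p` (resolved at fit
#' time when `NULL`).
#'
#' @param learning_rate positive step size.
#' @param first_moment_decay Adam beta1.
#' @param epochs number of passes over the data (>= 1).
#' @param batch_size mini-batch size, or `NULL` for `3 * p`.
#' @param seed integer seed for initialization and batch shuffling.
#' @return an object of class `optimizer_config`.
#' @export
optimizer_config <- function(learning_rate = 0.01, first_moment_decay = 0.95,
                             epochs = 200, batch_size = NULL, seed = 1L) {
  if (learning_rate <= 0) stop_invalid("learning_rate must be > 0", "invalid_parameter")
  if (epochs < 1) stop_invalid("epochs must be >= 1", "invalid_parameter")
  if (!is.null(batch_size) && batch_size < 1) {
    stop_invalid("batch_size must be >= 1", "invalid_parameter")
  }
  structure(list(learning_rate = learning_rate,
                 first_moment_decay = first_moment_decay,
                 second_moment_decay = 0.999, epsilon = 1e-8,
                 epochs = as.integer(epochs), batch_size = batch_size,
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Global L1 penalty (unscaled)
#'
#' Sum of absolute values over the trunk-and-heads parameter set P: all trunk
#' weights and per-layer intercepts plus the output-head weights and the
#' output-layer intercepts. The covariate skip connections and the treatment
#' coefficient are not in P. Also accepts a plain list of numeric arrays.
#'
#' @param x an `nn_model` or a list of numeric arrays.
#' @return nonnegative scalar.
#' @export
l1_penalty <- function(x) {
  if (inherits(x, "nn_model")) {
    sum(vapply(model_cores(x),
               function(core) sum(abs(unlist(core_penalty_params(core)))),
               numeric(1)))
  } else {
    sum(abs(unlist(x)))
  }
}

#' Targeted L1 penalty (unscaled)
#'
#' Sum of absolute values over the treatment head `Gamma_A` plus the first
#' hidden layer (weights and intercepts). For the double family only the
#' treatment network is counted.
#'
#' @param net an `nn_model`.
#' @return nonnegative scalar.
#' @export
targeted_penalty <- function(net) {
  stopifnot(inherits(net, "nn_model"))
  core <- if (net$family == "joint") net$core else net$treatment
  sum(abs(unlist(core_penalty_params(core, targeted = TRUE))))
}

clamp_prob <- function(g) pmin(pmax(g, 1e-7), 1 - 1e-7)

cross_entropy <- function(ghat, a) {
  g <- clamp_prob(ghat)
  -sum(a * log(g) + (1 - a) * log(1 - g))
}

#' Joint multi-task loss
#'
#' The total training objective of the joint family written as sums over the
#' n observations:
#' `a * sum((y - yhat)^2) + b * CE(a_vec, ghat) + cl1 * L1(P) + cl1tg * TG`,
#' with CE the negative Bernoulli log-likelihood (probabilities clamped to
#' \[1e-7, 1 - 1e-7\] inside the logarithms only).
#'
#' @param yhat outcome predictions.
#' @param y observed outcomes.
#' @param ghat fitted propensities in (0, 1).
#' @param a_vec 0/1 treatment vector.
#' @param loss a [loss_config()].
#' @param net the `nn_model` whose parameters enter the penalties.
#' @return scalar loss.
#' @export
joint_loss <- function(yhat, y, ghat, a_vec, loss, net) {
  stopifnot(length(yhat) == length(y), length(ghat) == length(a_vec))
  loss$a * sum((y - yhat)^2) + loss$b * cross_entropy(ghat, a_vec) +
    loss$cl1 * l1_penalty(net) + loss$cl1tg * targeted_penalty(net)
}

#' Separate losses of the double family
#'
#' `Ly` is the outcome network's squared-error loss plus its global L1
#' penalty; `LA` is the treatment network's cross-entropy plus its global L1
#' penalty plus the targeted penalty on its treatment head and first layer.
#'
#' @param net a [double_network()].
#' @param w covariate matrix.
#' @param a 0/1 treatment vector.
#' @param y outcome vector.
#' @param loss a [loss_config()].
#' @return named numeric vector `c(ly = ..., la = ...)`.
#' @export
dnn_losses <- function(net, w, a, y, loss) {
  stopifnot(inherits(net, "double_network"))
  f <- forward_double(net, w, a)
  ly <- sum((y - f$yhat)^2) +
    loss$cl1_y * sum(abs(unlist(core_penalty_params(net$outcome))))
  la <- cross_entropy(f$ghat, a) +
    loss$cl1_a * sum(abs(unlist(core_penalty_params(net$treatment)))) +
    loss$cl1tg * targeted_penalty(net)
  c(ly = ly, la = la)
}

## ---- internal training engine -------------------------------------------

## Flat parameter views of a core for the optimizer. Trunk tensors are named
## w1/b1/..., heads gamma_y/gamma_a, skips alpha/gamma, scalars
## alpha0/gamma0/beta_net.
core_to_flat <- function(core) {
  out <- list()
  for (l in seq_along(core$trunk)) {
    out[[paste0("w", l)]] <- core$trunk[[l]]$w
    out[[paste0("b", l)]] <- core$trunk[[l]]$b
  }
  for (nm in intersect(c("gamma_y", "alpha", "alpha0", "beta_net",
                         "gamma_a", "gamma", "gamma0"), names(core))) {
    out[[nm]] <- core[[nm]]
  }
  out
}

flat_to_core <- function(core, flat) {
  for (l in seq_along(core$trunk)) {
    core$trunk[[l]]$w <- flat[[paste0("w", l)]]
    core$trunk[[l]]$b <- flat[[paste0("b", l)]]
  }
  for (nm in intersect(c("gamma_y", "alpha", "alpha0", "beta_net",
                         "gamma_a", "gamma", "gamma0"), names(flat))) {
    core[[nm]] <- flat[[nm]]
  }
  core
}

## Batch objective + gradient of one core. Data terms are batch means; the
## L1 constants apply to the penalty sums unscaled (the usual deep-learning
## convention, which the printed penalty magnitudes presume).
core_step <- function(core, wb, ab, yb, a_w, b_w, lam1, lamtg, n_layers) {
  m <- nrow(wb)
  f <- forward_core(core, wb, ab, keep = TRUE)
  g <- list()
  obj_y <- 0; obj_a <- 0
  lh <- ncol(f$h)
  dz <- matrix(0, m, lh)
  if ("y" %in% core$heads) {
    res <- f$yhat - yb
    obj_y <- a_w * mean(res^2)
    dy <- (a_w * 2 / m) * res
    g$alpha0 <- sum(dy)
    g$beta_net <- sum(dy * ab)
    g$alpha <- drop(crossprod(wb, dy))
    g$gamma_y <- drop(crossprod(f$h, dy))
    dz <- dz + outer(dy, core$gamma_y)
  }
  if ("a" %in% core$heads) {
    obj_a <- b_w * cross_entropy(f$ghat, ab) / m
    dl <- (b_w / m) * (f$ghat - ab)
    g$gamma0 <- sum(dl)
    g$gamma <- drop(crossprod(wb, dl))
    g$gamma_a <- drop(crossprod(f$h, dl))
    dz <- dz + outer(dl, core$gamma_a)
  }
  for (l in rev(seq_len(n_layers))) {
    ds <- dz * (f$ss[[l]] > 0)
    z_prev <- if (l == 1) wb else f$zs[[l - 1]]
    g[[paste0("w", l)]] <- crossprod(z_prev, ds)
    g[[paste0("b", l)]] <- colSums(ds)
    if (l > 1) dz <- tcrossprod(ds, core$trunk[[l]]$w)
  }
  ## L1 subgradients over P (trunk + heads), targeted over gamma_a + layer 1
  pen <- 0
  for (l in seq_len(n_layers)) {
    wl <- core$trunk[[l]]$w; bl <- core$trunk[[l]]$b
    extra <- lam1 + if (l == 1) lamtg else 0
    g[[paste0("w", l)]] <- g[[paste0("w", l)]] + extra * sign(wl)
    g[[paste0("b", l)]] <- g[[paste0("b", l)]] + extra * sign(bl)
    pen <- pen + extra * (sum(abs(wl)) + sum(abs(bl)))
  }
  if ("y" %in% core$heads) {
    g$gamma_y <- g$gamma_y + lam1 * sign(core$gamma_y)
    g$alpha0 <- g$alpha0 + lam1 * sign(core$alpha0)
    pen <- pen + lam1 * (sum(abs(core$gamma_y)) + abs(core$alpha0))
  }
  if ("a" %in% core$heads) {
    g$gamma_a <- g$gamma_a + (lam1 + lamtg) * sign(core$gamma_a)
    g$gamma0 <- g$gamma0 + lam1 * sign(core$gamma0)
    pen <- pen + (lam1 + lamtg) * sum(abs(core$gamma_a)) + lam1 * abs(core$gamma0)
  }
  list(grad = g, obj = obj_y + obj_a + pen,
       obj_y = obj_y, obj_a = obj_a, obj_pen = pen)
}

train_core <- function(core, w, a, y, a_w, b_w, lam1, lamtg, opt, batch_size) {
  n <- nrow(w)
  n_layers <- length(core$trunk)
  flat <- core_to_flat(core)
  mstate <- lapply(flat, function(p) p * 0)
  vstate <- mstate
  b1 <- opt$first_moment_decay; b2 <- opt$second_moment_decay
  lr <- opt$learning_rate; eps <- opt$epsilon
  t_step <- 0
  log <- matrix(NA_real_, opt$epochs, 4,
                dimnames = list(NULL, c("loss", "outcome", "treatment", "penalty")))
  for (epoch in seq_len(opt$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    acc <- c(0, 0, 0, 0); nb <- 0
    for (s in starts) {
      ix <- ord[s:min(s + batch_size - 1, n)]
      st <- core_step(core, w[ix, , drop = FALSE], a[ix], y[ix],
                      a_w, b_w, lam1, lamtg, n_layers)
      if (!is.finite(st$obj)) {
        stop(errorCondition(
          sprintf("training diverged (non-finite loss) at epoch %d, batch %d",
                  epoch, nb + 1),
          class = c("nnaipw_divergence", "nnaipw_error")))
      }
      t_step <- t_step + 1
      corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
      for (nm in names(flat)) {
        gr <- st$grad[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr * gr
        flat[[nm]] <- flat[[nm]] -
          lr * (mstate[[nm]] / corr1) / (sqrt(vstate[[nm]] / corr2) + eps)
      }
      core <- flat_to_core(core, flat)
      acc <- acc + c(st$obj, st$obj_y, st$obj_a, st$obj_pen); nb <- nb + 1
    }
    log[epoch, ] <- acc / nb
  }
  list(core = core, log = as.data.frame(log))
}

## Full-data value of the optimizer's objective (per-observation-mean data
## terms + unscaled penalties), for before/after comparison.
core_objective <- function(core, w, a, y, a_w, b_w, lam1, lamtg) {
  n <- nrow(w)
  f <- forward_core(core, w, a)
  obj <- 0
  if ("y" %in% core$heads) obj <- obj + a_w * mean((f$yhat - y)^2)
  if ("a" %in% core$heads) obj <- obj + b_w * cross_entropy(f$ghat, a) / n
  obj + lam1 * sum(abs(unlist(core_penalty_params(core)))) +
    lamtg * sum(abs(unlist(core_penalty_params(core, targeted = TRUE))))
}

#' Fit a network to data
#'
#' Trains the nuisance model(s) by seeded-shuffle mini-batch Adam. Covariates
#' are standardized to mean 0 / variance 1 (training statistics, stored on
#' the returned network and reapplied by every later forward pass); the
#' outcome is left on its own scale. The joint family minimizes the
#' multi-task loss; the double family trains its outcome and treatment
#' networks separately on their own losses. The optimizer's objective uses
#' per-observation-mean data terms with the L1 constants applied to the
#' penalty sums unscaled, the usual deep-learning convention, so a given
#' penalty constant has the same regularization strength at every sample
#' size.
#'
#' @param net an initialized [joint_network()] or [double_network()] (used
#'   for its architecture; parameters are re-initialized from
#'   `optimizer$seed` so a fit is fully determined by data + configs).
#' @param w covariate matrix.
#' @param a 0/1 treatment vector.
#' @param y outcome vector.
#' @param loss a [loss_config()].
#' @param optimizer an [optimizer_config()].
#' @return an object of class `nn_fit`: `net` (trained), `predictions` (a
#'   [nuisance_predictions()] with in-sample `ghat`, `qhat1`, `qhat0`),
#'   `log` (per-epoch mean batch objective and components), `initial_loss`,
#'   `final_loss` (full-data objective before/after training).
#' @export
fit_network <- function(net, w, a, y, loss = loss_config(),
                        optimizer = optimizer_config()) {
  stopifnot(inherits(net, "nn_model"), inherits(loss, "loss_config"),
            inherits(optimizer, "optimizer_config"))
  if (nrow(w) != length(a) || length(a) != length(y)) {
    stop_invalid("w, a, y sizes do not match", "invalid_input")
  }
  if (ncol(w) != net$p) {
    stop_invalid("covariate matrix width does not match network input size",
                 "invalid_input")
  }
  n <- nrow(w)
  center <- colMeans(w)
  scale <- apply(w, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  ws <- sweep(sweep(w, 2, center, "-"), 2, scale, "/")
  batch_size <- if (is.null(optimizer$batch_size)) 3L * net$p else optimizer$batch_size

  fitted <- with_seed(optimizer$seed, {
    if (net$family == "joint") {
      core <- init_core(net$p, net$widths, c("y", "a"))
      init_obj <- core_objective(core, ws, a, y, loss$a, loss$b,
                                 loss$cl1, loss$cl1tg)
      tr <- train_core(core, ws, a, y, loss$a, loss$b,
                       loss$cl1, loss$cl1tg, optimizer, batch_size)
      net$core <- tr$core
      final_obj <- core_objective(tr$core, ws, a, y, loss$a, loss$b,
                                  loss$cl1, loss$cl1tg)
      list(net = net, log = tr$log, initial = init_obj, final = final_obj)
    } else {
      core_y <- init_core(net$p, net$widths, "y")
      core_a <- init_core(net$p, net$widths, "a")
      init_obj <- core_objective(core_y, ws, a, y, 1, 0, loss$cl1_y, 0) +
        core_objective(core_a, ws, a, y, 0, 1, loss$cl1_a, loss$cl1tg)
      tr_y <- train_core(core_y, ws, a, y, 1, 0, loss$cl1_y, 0,
                         optimizer, batch_size)
      tr_a <- train_core(core_a, ws, a, y, 0, 1, loss$cl1_a,
                         loss$cl1tg, optimizer, batch_size)
      net$outcome <- tr_y$core
      net$treatment <- tr_a$core
      final_obj <- core_objective(tr_y$core, ws, a, y, 1, 0, loss$cl1_y, 0) +
        core_objective(tr_a$core, ws, a, y, 0, 1, loss$cl1_a, loss$cl1tg)
      log <- tr_y$log
      log$loss <- log$loss + tr_a$log$loss
      log$treatment <- tr_a$log$treatment
      log$penalty <- log$penalty + tr_a$log$penalty
      list(net = net, log = log, initial = init_obj, final = final_obj)
    }
  })
  net <- fitted$net
  net$standardize <- list(center = center, scale = scale)
  fw <- forward_model(net, w, a)
  cf <- predict_counterfactuals(net, w)
  preds <- nuisance_predictions(fw$ghat, cf$qhat1, cf$qhat0)
  structure(list(net = net, predictions = preds,
                 log = cbind(epoch = seq_len(nrow(fitted$log)), fitted$log),
                 initial_loss = fitted$initial, final_loss = fitted$final),
            class = "nn_fit")
}

#' @export
print.nn_fit <- function(x, ...) {
  print(x$net)
  cat("  objective:", format(x$initial_loss, digits = 5), "->",
      format(x$final_loss, digits = 5), "over",
      nrow(x$log), "epochs\n")
  invisible(x)
}
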