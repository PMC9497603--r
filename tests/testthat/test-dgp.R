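test_that("covariate draws match the AR(1) covariance structure", {
  expect_error(draw_covariates(100, 5, rho = 1), class = "invalid_parameter")
  expect_error(draw_covariates(100, 5, rho = -0.2), class = "invalid_parameter")

  # rho = 0: identity covariance
  x <- draw_covariates(5000, 6, rho = 0, seed = 1)
  off <- abs(cor(x)[upper.tri(diag(6))])
  expect_lt(mean(off), 0.05)

  # rho = 0.5 adjacent-column correlation, unit variances
  x <- draw_covariates(7500, 12, rho = 0.5, seed = 2)
  cc <- cor(x)
  adj <- mean(cc[cbind(1:11, 2:12)])
  expect_equal(adj, 0.5, tolerance = 0.02 / 0.5)
  expect_true(all(abs(apply(x, 2, var) - 1) < 0.05))
  # lag-2 correlation converges to rho^2
  lag2 <- mean(cc[cbind(1:10, 3:12)])
  expect_lt(abs(lag2 - 0.25), 0.02)

  # reproducible given seed
  expect_identical(draw_covariates(50, 4, 0.3, seed = 9),
                   draw_covariates(50, 4, 0.3, seed = 9))
})

test_that("step functions evaluate the printed indicator sums, overlaps adding", {
  expect_equal(step_g(-2, 1), -2)
  expect_equal(step_g(3, 1), 3)
  expect_equal(step_h(0.5, 1), -2)
  expect_equal(step_h(2, 1), 3)
  expect_equal(step_g(0.5, 2), 1)
  expect_equal(step_h(0.5, 2), 0)
  # breakpoints where two indicators are both true: contributions add
  expect_equal(step_g(-1, 1), -3)  # -2 + (-1)
  expect_equal(step_g(0, 1), 0)    # -1 + 1
  expect_equal(step_g(2, 1), 4)    # 1 + 3
  expect_equal(step_h(0, 1), -7)   # -5 + (-2)
  expect_equal(step_h(1, 1), 1)    # -2 + 3
  # vectorized
  expect_equal(step_g(c(-2, 3), 1), c(-2, 3))
})

test_that("pair features select, pair and transform reproducibly", {
  blk <- draw_covariates(50, 8, 0, seed = 3)
  expect_error(make_pair_features(blk[, 1, drop = FALSE], 0.5),
               class = "degenerate_block")

  empty <- make_pair_features(blk, 0)
  expect_equal(ncol(empty$features), 0)
  expect_equal(nrow(empty$record), 0)

  # hand evaluations of individual catalogue entries
  lib <- nonlinear_library()
  expect_equal(lib[[5]](3, 2, 1), 9)    # g(3) * h(2) = 3 * 3
  expect_equal(lib[[4]](1, 0), 16)      # (1 + 0 + 3)^2
  expect_equal(lib[[1]](2, 1), exp(1))
  expect_equal(lib[[2]](1, 0), 0.5)
  expect_equal(lib[[3]](0, 5), 8)       # (0 + 2)^3

  # the record reconstructs the features exactly
  pf <- make_pair_features(blk, 0.5, seed = 11)
  expect_equal(ncol(pf$features), nrow(pf$record))
  expect_equal(ncol(pf$features), ceiling(ceiling(0.5 * 8) / 2))
  for (j in seq_len(nrow(pf$record))) {
    r <- pf$record[j, ]
    rebuilt <- lib[[r$entry]](blk[, r$col1], blk[, r$col2],
                              if (is.na(r$variant)) 1 else r$variant)
    expect_equal(pf$features[, j], rebuilt)
  }
  # selected columns are within the block and pairs are reproducible
  expect_true(all(c(pf$record$col1, pf$record$col2) %in% 1:8))
  expect_identical(pf, make_pair_features(blk, 0.5, seed = 11))
})

test_that("coefficient draws are uniform over the requested range", {
  expect_error(sample_coefficients(1, 0, 5), class = "invalid_parameter")
  expect_equal(sample_coefficients(0.1, 0.1, 5, seed = 1), rep(0.1, 5))
  expect_length(sample_coefficients(0, 1, 0, seed = 1), 0)
  draws <- sample_coefficients(0.1, 1, 10000, seed = 2)
  expect_equal(mean(draws), 0.55, tolerance = 0.02 / 0.55)
  expect_true(all(draws >= 0.1 & draws <= 1))
})

test_that("treatment assignment follows the logistic propensity", {
  expect_error(sample_treatment(c(0, NA)), class = "invalid_input")
  t0 <- sample_treatment(rep(0, 10), seed = 1)
  expect_equal(t0$propensity, rep(0.5, 10))
  t2 <- sample_treatment(rep(20, 500), seed = 2)
  expect_true(all(t2$propensity > 0.9999))
  expect_gt(mean(t2$a), 0.99)
  # law of large numbers: treated fraction tracks the mean propensity
  eta <- rep(c(-1, 0, 0.5, 2), length.out = 10000)
  tr <- sample_treatment(eta, seed = 3)
  expect_equal(mean(tr$a), mean(tr$propensity), tolerance = 0.02 / mean(tr$propensity))
})

test_that("outcome construction gives a constant additive effect", {
  n <- 20
  z <- rep(0, n)
  out <- generate_outcome(rep(c(0, 1), 10), z, z, beta = 1, intercept = 3, noise = z)
  expect_equal(out$y0, rep(3, n))
  expect_equal(out$y1, rep(4, n))
  expect_equal(out$y, 3 + rep(c(0, 1), 10))

  noise <- rnorm(n)
  conf <- rnorm(n)
  out <- generate_outcome(rbinom(n, 1, 0.5), conf, z, beta = 2.5, intercept = 3,
                          noise = noise)
  expect_identical(out$y1, out$y0 + 2.5)
  expect_identical(out$mu0 + noise, out$y0)
  expect_error(generate_outcome(c(0, 1), z, z, 1, 3, z), class = "invalid_input")
})

test_that("simulate_scenario assembles roles, treatment and outcome coherently", {
  cfg <- scenario_config(n = 750, p = 32, conf_range = c(0.1, 0.1),
                         iv_range = c(0.1, 0.1), seed = 5)
  sim <- simulate_scenario(cfg)
  expect_equal(as.integer(table(sim$roles)[c("confounder", "iv", "y_predictor",
                                             "irrelevant")]),
               rep(8L, 4))
  expect_true(all(sim$a %in% 0:1))
  expect_true(all(sim$g_true > 0 & sim$g_true < 1))
  # conservation and constant per-unit effect (exact, by construction)
  expect_identical(sim$y, ifelse(sim$a == 1, sim$y1, sim$y0))
  expect_identical(sim$y1, sim$y0 + cfg$beta)
  # bitwise reproducibility
  expect_identical(sim, simulate_scenario(cfg))
})

test_that("degenerate scenario reduces to a randomized trial", {
  sim <- simulate_scenario(null_scenario(seed = 8, n = 2000))
  expect_equal(sim$eta, rep(0, 2000))
  expect_equal(sim$g_true, rep(0.5, 2000))
  expect_identical(sim$mu0, rep(3, 2000))  # Y0 = 3 + noise
  expect_equal(sd(sim$y0 - 3), 1, tolerance = 0.08)
  expect_equal(mean(sim$a), 0.5, tolerance = 0.1)
})

test_that("true propensities are calibrated against realized treatment", {
  cfg <- scenario_config(n = 7500, p = 32, conf_range = c(0.1, 1),
                         iv_range = c(0.1, 1), seed = 13)
  sim <- simulate_scenario(cfg)
  dec <- cut(sim$g_true, stats::quantile(sim$g_true, 0:10 / 10),
             include.lowest = TRUE)
  for (lev in levels(dec)) {
    ix <- dec == lev
    if (sum(ix) < 30) next
    pbar <- mean(sim$g_true[ix])
    se <- sqrt(pbar * (1 - pbar) / sum(ix))
    expect_lt(abs(mean(sim$a[ix]) - pbar), 3 * se + 1e-12)
  }
})

test_that("eta and the outcome depend only on their designated blocks", {
  cfg <- tiny_scenario(seed = 21, n = 300)
  sim <- simulate_scenario(cfg)
  idx <- split(seq_len(cfg$p), factor(sim$roles, unique(sim$roles)))
  lib <- nonlinear_library()
  rebuild <- function(block, record, coefs) {
    if (nrow(record) == 0) return(rep(0, nrow(block)))
    feats <- vapply(seq_len(nrow(record)), function(j) {
      r <- record[j, ]
      lib[[r$entry]](block[, r$col1], block[, r$col2],
                     if (is.na(r$variant)) 1 else r$variant)
    }, numeric(nrow(block)))
    drop(matrix(feats, nrow = nrow(block)) %*% coefs)
  }
  # eta rebuilt from the confounder and iv blocks alone
  eta2 <- rebuild(sim$w[, idx$confounder, drop = FALSE], sim$transformations$fa,
                  sim$coefficients$gamma_c) +
    rebuild(sim$w[, idx$iv, drop = FALSE], sim$transformations$ga,
            sim$coefficients$gamma_iv)
  expect_equal(eta2, sim$eta)
  # mu0 rebuilt from the confounder and y-predictor blocks alone:
  # instruments and irrelevant covariates never touch the outcome
  mu2 <- cfg$intercept +
    rebuild(sim$w[, idx$confounder, drop = FALSE], sim$transformations$fy,
            sim$coefficients$gamma_c2) +
    rebuild(sim$w[, idx$y_predictor, drop = FALSE], sim$transformations$gy,
            sim$coefficients$gamma_y)
  expect_equal(mu2, sim$mu0)
})

test_that("scenario configuration validates its invariants", {
  expect_error(scenario_config(n = 1), class = "invalid_parameter")
  expect_error(scenario_config(p = 32, block_sizes = c(8, 8, 8, 9)),
               class = "invalid_parameter")
  expect_error(scenario_config(rho = 1), class = "invalid_parameter")
  expect_error(scenario_config(conf_range = c(1, 0.1)), class = "invalid_parameter")
  expect_error(scenario_config(nonlinear_fraction = 1.2), class = "invalid_parameter")
  grid <- scenario_grid(seed = 1)
  expect_length(grid, 8)
  expect_equal(sum(vapply(grid, function(s) s$n == 750, TRUE)), 4)
})
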