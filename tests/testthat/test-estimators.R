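random_preds <- function(n, seed = 1) {
  set.seed(seed)
  nuisance_predictions(runif(n, 0.2, 0.8), rnorm(n, 1), rnorm(n))
}

test_that("the prediction container enforces positivity and lengths", {
  expect_error(nuisance_predictions(c(0.5, 0), 1:2, 1:2),
               class = "positivity_violation")
  expect_error(nuisance_predictions(c(0.5, 1), 1:2, 1:2),
               class = "positivity_violation")
  expect_error(nuisance_predictions(0.5, 1:2, 1:2), class = "invalid_input")
  p <- nuisance_predictions(c(0.4, 0.6), c(2, 2), c(1, 1))
  expect_s3_class(p, "nuisance_predictions")
})

test_that("AIPW reduces correctly in closed-form cases", {
  # hand arithmetic: n = 2, unit 1 treated (y=2, q1=1), unit 2 control (y=0, q0=1)
  preds <- nuisance_predictions(c(0.5, 0.5), c(1, 1), c(1, 1))
  expect_equal(aipw(c(2, 0), c(1, 0), preds), 2)

  # zero residuals: augmentation vanishes, aipw = plug-in
  set.seed(2)
  n <- 50
  a <- rbinom(n, 1, 0.5); a[1] <- 1; a[2] <- 0
  q1 <- rnorm(n, 2); q0 <- rnorm(n)
  y <- ifelse(a == 1, q1, q0)
  preds <- nuisance_predictions(runif(n, 0.2, 0.8), q1, q0)
  expect_equal(aipw(y, a, preds), mean(q1 - q0))
  expect_equal(naipw(y, a, preds), mean(q1 - q0))
  expect_equal(plug_in(preds), mean(q1 - q0))

  # qhat = 0, ghat = 0.5: Horvitz-Thompson form
  y <- rnorm(n)
  preds0 <- nuisance_predictions(rep(0.5, n), rep(0, n), rep(0, n))
  expect_equal(aipw(y, a, preds0), 2 * (mean(a * y) - mean((1 - a) * y)))
  expect_equal(aipw(y, a, preds0), ipw(y, a, preds0))
})

test_that("normalized and unnormalized AIPW agree at constant ghat = n1/n", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 60
    a <- rbinom(n, 1, 0.6); a[1] <- 1; a[2] <- 0
    y <- rnorm(n, 1 + a)
    q1 <- rnorm(n); q0 <- rnorm(n)
    preds <- nuisance_predictions(rep(mean(a), n), q1, q0)
    expect_equal(naipw(y, a, preds), aipw(y, a, preds))
    expect_equal(nipw(y, a, preds), ipw(y, a, preds))
  }
})

test_that("IPW closed forms and translation equivariance hold", {
  # balanced arms, ghat = 0.5, y = a
  a <- rep(c(1, 0), 10)
  y <- a
  preds <- nuisance_predictions(rep(0.5, 20), rep(0, 20), rep(0, 20))
  expect_equal(ipw(y, a, preds), 1)
  expect_equal(nipw(y, a, preds), 1)
  expect_equal(plug_in(nuisance_predictions(rep(0.5, 5), rep(3.2, 5),
                                            rep(1.2, 5))), 2)

  # adding c to y and both qhats leaves the centered estimators unchanged
  set.seed(9)
  n <- 80
  a <- rbinom(n, 1, 0.5); a[1] <- 1; a[2] <- 0
  y <- rnorm(n)
  preds <- random_preds(n, seed = 10)
  shifted <- nuisance_predictions(preds$ghat, preds$qhat1 + 5, preds$qhat0 + 5)
  for (f in list(aipw, naipw, nipw)) {
    expect_equal(f(y + 5, a, shifted), f(y, a, preds))
  }
  expect_equal(plug_in(shifted), plug_in(preds))
})

test_that("degenerate arms raise an undefined-estimator condition", {
  preds <- nuisance_predictions(rep(0.5, 4), rep(1, 4), rep(0, 4))
  expect_error(naipw(rnorm(4), rep(1, 4), preds), class = "undefined_estimator")
  expect_error(nipw(rnorm(4), rep(0, 4), preds), class = "undefined_estimator")
  expect_error(aipw(rnorm(4), c(0, 1, 2, 1), preds), class = "invalid_input")
})

test_that("influence-function intervals match the sd/sqrt(n) oracle", {
  # constant contributions: degenerate interval at the point
  preds <- nuisance_predictions(rep(0.5, 4), rep(2, 4), rep(1, 4))
  est <- asymptotic_ci("plug_in", rnorm(4), c(1, 0, 1, 0), preds)
  expect_equal(est$stderr, 0)
  expect_equal(est$ci_lower, est$point)
  expect_equal(est$ci_upper, est$point)

  # hand-set 4-unit contribution vector (plug-in contributions are q1 - q0)
  preds <- nuisance_predictions(rep(0.5, 4), c(1, 2, 3, 4), rep(0, 4))
  est <- asymptotic_ci("plug_in", rnorm(4), c(1, 0, 1, 0), preds)
  expect_equal(est$point, 2.5)
  expect_equal(est$stderr, sd(1:4) / 2)
  expect_equal(est$ci_lower, 2.5 - 1.96 * sd(1:4) / 2)

  # the interval always contains the point, and mean(contributions) = estimate
  set.seed(4)
  n <- 30
  a <- rbinom(n, 1, 0.5); a[1] <- 1; a[2] <- 0
  y <- rnorm(n)
  preds <- random_preds(n, seed = 5)
  for (m in c("aipw", "naipw", "ipw", "nipw", "plug_in")) {
    est <- asymptotic_ci(m, y, a, preds)
    expect_true(est$ci_lower <= est$point && est$point <= est$ci_upper)
    ref <- switch(m, aipw = aipw(y, a, preds), naipw = naipw(y, a, preds),
                  ipw = ipw(y, a, preds), nipw = nipw(y, a, preds),
                  plug_in = plug_in(preds))
    expect_equal(est$point, ref)
  }
})

test_that("AIPW is doubly robust under one correct nuisance model", {
  # correct propensities, useless outcome model - and vice versa
  reps <- 50
  ests_g <- numeric(reps); ests_q <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- scenario_config(n = 7500, p = 32, conf_range = c(0.1, 0.1),
                           iv_range = c(0.1, 0.1), seed = 1000 + r)
    sim <- simulate_scenario(cfg)
    zeros <- rep(0, cfg$n)
    preds_g <- nuisance_predictions(sim$g_true, zeros, zeros)
    ests_g[r] <- aipw(sim$y, sim$a, preds_g)
    preds_q <- nuisance_predictions(rep(0.5, cfg$n), sim$mu0 + cfg$beta, sim$mu0)
    ests_q[r] <- aipw(sim$y, sim$a, preds_q)
  }
  expect_lt(abs(mean(ests_g) - 1), 3 * sd(ests_g) / sqrt(reps))
  expect_lt(abs(mean(ests_q) - 1), 3 * sd(ests_q) / sqrt(reps))
})
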