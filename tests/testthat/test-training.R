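test_that("L1 penalties sum the designated parameter sets only", {
  net <- zero_net(joint_network(4, c(3, 3), seed = 1))
  expect_equal(l1_penalty(net), 0)
  expect_equal(l1_penalty(list(rep(-1, 10))), 10)

  # targeted set: Gamma_A + first layer; everything else is huge and ignored
  net$core$alpha <- rep(100, 4)
  net$core$gamma <- rep(100, 4)
  net$core$beta_net <- 100
  net$core$trunk[[2]]$w[] <- 100
  expect_equal(targeted_penalty(net), 0)
  net$core$gamma_a[1:3] <- 1          # lh = 3
  net$core$gamma_a[3] <- -1
  net$core$trunk[[1]]$w[1:2, ] <- 0.5 # 6 entries of 0.5
  expect_equal(targeted_penalty(net), 3 + 3)

  # brute-force oracle on a random network
  rnet <- joint_network(5, c(4, 3), seed = 7)
  p_set <- c(lapply(rnet$core$trunk, function(l) c(l$w, l$b)),
             list(rnet$core$gamma_y, rnet$core$alpha0,
                  rnet$core$gamma_a, rnet$core$gamma0))
  expect_equal(l1_penalty(rnet), sum(abs(unlist(p_set))))
  tg_set <- c(rnet$core$gamma_a, rnet$core$trunk[[1]]$w, rnet$core$trunk[[1]]$b)
  expect_equal(targeted_penalty(rnet), sum(abs(tg_set)))
})

test_that("joint loss decomposes into its four terms", {
  net <- joint_network(3, 2, seed = 2)
  n <- 30
  y <- rnorm(n); a <- rbinom(n, 1, 0.5)
  yhat <- rnorm(n); ghat <- runif(n, 0.1, 0.9)
  lc <- loss_config(a = 2, b = 0.5, cl1 = 0.3, cl1tg = 0.7)
  total <- joint_loss(yhat, y, ghat, a, lc, net)
  parts <- 2 * sum((y - yhat)^2) -
    0.5 * sum(a * log(ghat) + (1 - a) * log(1 - ghat)) +
    0.3 * l1_penalty(net) + 0.7 * targeted_penalty(net)
  expect_equal(total, parts, tolerance = 1e-8)

  # closed forms
  expect_equal(joint_loss(y, y, ghat, a, loss_config(b = 0), zero_net(net)), 0)
  expect_equal(joint_loss(yhat, y, rep(0.5, n), a, loss_config(a = 0),
                          zero_net(net)),
               n * log(2))
})

test_that("double-family losses are separate and recover unpenalized forms", {
  net <- zero_net(double_network(3, 2, seed = 1))
  n <- 20
  w <- matrix(rnorm(n * 3), n, 3)
  a <- rbinom(n, 1, 0.5)
  y <- rep(0, n)
  lc <- loss_config(cl1 = 0, cl1tg = 0)
  l0 <- dnn_losses(net, w, a, y, lc)
  expect_equal(unname(l0["ly"]), 0)          # zero net predicts 0 = y
  expect_equal(unname(l0["la"]), n * log(2)) # ghat = 0.5 everywhere

  # perturbing the outcome network never changes LA
  net2 <- net
  net2$outcome$gamma_y[] <- 3
  net2$outcome$trunk[[1]]$w[] <- 1
  expect_equal(dnn_losses(net2, w, a, y, lc)["la"], l0["la"])

  # penalties act on their own networks
  lc2 <- loss_config(cl1 = 1, cl1tg = 2)
  l2 <- dnn_losses(net2, w, a, y, lc2)
  sse2 <- sum(forward_double(net2, w, a)$yhat^2)  # y = 0
  expect_equal(unname(l2["ly"]),
               sse2 + sum(abs(net2$outcome$gamma_y)) +
                 sum(abs(net2$outcome$trunk[[1]]$w)))
  expect_equal(l2["la"], l0["la"])  # treatment net still all zero
})

test_that("fitting pure-intercept data recovers the marginal means", {
  set.seed(5)
  n <- 300
  w <- matrix(rnorm(n * 4), n, 4)
  y <- rep(2, n) + rnorm(n, sd = 0.01)
  a <- rbinom(n, 1, 0.5)
  fit <- fit_network(joint_network(4, c(4, 4)), w, a, y,
                     loss_config(), quick_opt(seed = 2, epochs = 200))
  f <- forward_joint(fit$net, w, a)
  expect_lt(abs(mean(f$yhat) - 2), 0.1)
  expect_lt(abs(mean(f$ghat) - mean(a)), 0.05)
})

test_that("a dominant targeted penalty crushes the targeted parameter sets", {
  sim <- simulate_scenario(tiny_scenario(seed = 31, n = 250))
  fit0 <- fit_network(joint_network(8, c(8, 8)), sim$w, sim$a, sim$y,
                      loss_config(cl1 = 0, cl1tg = 0), quick_opt(seed = 4))
  fit_big <- fit_network(joint_network(8, c(8, 8)), sim$w, sim$a, sim$y,
                         loss_config(cl1 = 0, cl1tg = 1000), quick_opt(seed = 4))
  expect_lt(targeted_penalty(fit_big$net), 0.01 * targeted_penalty(fit0$net))
})

test_that("fitted targeted-set size is non-increasing in the targeted constant", {
  sim <- simulate_scenario(tiny_scenario(seed = 33, n = 250))
  tg <- vapply(c(0, 0.1, 0.7, 10), function(cl1tg) {
    fit <- fit_network(joint_network(8, c(8, 8)), sim$w, sim$a, sim$y,
                       loss_config(cl1 = 0.01, cl1tg = cl1tg),
                       quick_opt(seed = 6))
    targeted_penalty(fit$net)
  }, numeric(1))
  expect_true(all(diff(tg) <= 0))
})

test_that("training is deterministic given the seed and reduces the objective", {
  sim <- simulate_scenario(tiny_scenario(seed = 35, n = 250))
  fit1 <- fit_network(joint_network(8, c(8, 8)), sim$w, sim$a, sim$y,
                      loss_config(cl1 = 0.05, cl1tg = 0.1), quick_opt(seed = 9))
  fit2 <- fit_network(joint_network(8, c(8, 8)), sim$w, sim$a, sim$y,
                      loss_config(cl1 = 0.05, cl1tg = 0.1), quick_opt(seed = 9))
  expect_identical(fit1$final_loss, fit2$final_loss)
  expect_identical(fit1$net, fit2$net)
  expect_identical(fit1$predictions, fit2$predictions)
  expect_lt(fit1$final_loss, fit1$initial_loss)
  # double family too
  d1 <- fit_network(double_network(8, c(8, 8)), sim$w, sim$a, sim$y,
                    loss_config(cl1 = 0.05, cl1tg = 0.1), quick_opt(seed = 9))
  d2 <- fit_network(double_network(8, c(8, 8)), sim$w, sim$a, sim$y,
                    loss_config(cl1 = 0.05, cl1tg = 0.1), quick_opt(seed = 9))
  expect_identical(d1$net, d2$net)
  expect_lt(d1$final_loss, d1$initial_loss)
})

test_that("configs validate their invariants", {
  expect_error(loss_config(a = 0, b = 0), class = "invalid_parameter")
  expect_error(loss_config(cl1 = -1), class = "invalid_parameter")
  expect_error(optimizer_config(learning_rate = 0), class = "invalid_parameter")
  expect_error(optimizer_config(epochs = 0), class = "invalid_parameter")
  expect_error(fit_network(joint_network(3, 2), matrix(0, 4, 3), c(0, 1),
                           rnorm(4)),
               class = "invalid_input")
})
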