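# Shared fixtures: small scenarios and cheap optimizer settings so unit
# tests stay fast; all seeds fixed.

tiny_scenario <- function(seed = 42L, n = 200, ...) {
  scenario_config(n = n, p = 8, block_sizes = rep(2, 4), seed = seed, ...)
}

# Scenario with no covariate effects at all: eta = 0, Y = 3 + A + noise.
null_scenario <- function(seed = 7L, n = 400) {
  scenario_config(n = n, p = 8, block_sizes = rep(2, 4),
                  conf_range = c(0, 0), iv_range = c(0, 0),
                  nonlinear_fraction = 0, seed = seed)
}

quick_opt <- function(seed = 1L, epochs = 60, ...) {
  optimizer_config(epochs = epochs, seed = seed, ...)
}

# Set every parameter of a network to zero (keeps architecture).
zero_core <- function(core) {
  for (l in seq_along(core$trunk)) {
    core$trunk[[l]]$w[] <- 0
    core$trunk[[l]]$b[] <- 0
  }
  for (nm in intersect(c("gamma_y", "alpha", "gamma_a", "gamma"), names(core))) {
    core[[nm]][] <- 0
  }
  for (nm in intersect(c("alpha0", "gamma0", "beta_net"), names(core))) {
    core[[nm]] <- 0
  }
  core
}

zero_net <- function(net) {
  if (net$family == "joint") {
    net$core <- zero_core(net$core)
  } else {
    net$outcome <- zero_core(net$outcome)
    net$treatment <- zero_core(net$treatment)
  }
  net
}

# Brute-force distance correlation straight from the double-centering
# definition, written with explicit loops: the independent oracle for
# distance_correlation().
dcor_bruteforce <- function(u, v) {
  n <- length(u)
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- abs(u[i] - u[j])
    B[i, j] <- abs(v[i] - v[j])
  }
  cen <- function(M) {
    out <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      out[i, j] <- M[i, j] - mean(M[i, ]) - mean(M[, j]) + mean(M)
    }
    out
  }
  A <- cen(A); B <- cen(B)
  dcov2 <- sum(A * B) / n^2
  dvaru <- sum(A * A) / n^2
  dvarv <- sum(B * B) / n^2
  if (dvaru == 0 || dvarv == 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvaru * dvarv))
}
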