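# Independent oracles used across tests.

# Exact pinball-loss (quantile regression) minimizer by basis enumeration:
# a solution interpolates p observations, so for p = 2 every point pair is
# a candidate basis. Exact for data in general position; O(n^2) so only for
# small fixtures.
pinball_pairs_oracle <- function(y, x, tau) {
  n <- length(y)
  best <- NULL; bestv <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[i] == x[j]) next
    b1 <- (y[j] - y[i]) / (x[j] - x[i])
    b0 <- y[i] - b1 * x[i]
    r <- y - b0 - b1 * x
    v <- sum(r * (tau - (r < 0)))
    if (v < bestv) { bestv <- v; best <- c(b0, b1) }
  }
  list(coef = best, obj = bestv)
}

# Numerical integration of the mortality ODE dN/ddg = -exp(b0) dg^b1 N^b2
# with an adaptive solver; oracle for the closed-form trajectory.
ode_trajectory_oracle <- function(ode_params, N0, dg_grid) {
  b0 <- ode_params[1]; b1 <- ode_params[2]; b2 <- ode_params[3]
  rhs <- function(dg, state, parms) list(-exp(b0) * dg^b1 * state[1]^b2)
  out <- deSolve::ode(y = c(N = N0), times = dg_grid, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-8)
  unname(out[, "N"])
}

# Random admissible ODE parameter sets (finite attractor domain).
random_ode_params <- function(n, seed) {
  set.seed(seed)
  data.frame(b0 = runif(n, -12, -4),
             b1 = runif(n, 0.2, 1.5),
             b2 = runif(n, 1.3, 3.0))
}

# Mean +/- 2 Monte-Carlo-SE check for parameter recovery over replicates.
expect_recovers <- function(estimates, truth, label) {
  est <- estimates[stats::complete.cases(estimates), , drop = FALSE]
  m <- colMeans(est)
  mcse <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  for (j in seq_along(truth)) {
    expect_lt(abs(m[j] - truth[j]), 2 * mcse[j] + 1e-12,
              label = sprintf("%s: parameter %s (mean %.4g, truth %.4g, MC SE %.4g)",
                              label, colnames(est)[j], m[j], truth[j], mcse[j]))
  }
  invisible(list(mean = m, mcse = mcse))
}
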