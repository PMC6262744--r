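fake_lme_fit <- function(b0, b1, se0, n = 100) {
  structure(list(beta0 = b0, beta1 = b1, se_beta0 = se0, se_beta1 = 0.05,
                 n_obs = n,
                 plot_effects = data.frame(plot_id = "p1", u0 = 0, u1 = 0)),
            class = "lme_fit")
}

test_that("upper-CI line shifts the intercept by z times its SE", {
  f <- fake_lme_fit(11.0, -1.3, 0.2)
  l <- line_from_upper_ci(f)
  expect_equal(l$intercept, 11 + 1.96 * 0.2)
  expect_equal(l$slope, -1.3)
  expect_equal(l$intercept_unshifted, 11)

  expect_equal(line_from_upper_ci(fake_lme_fit(11, -1.3, 0))$intercept, 11)

  # a wider alpha shifts less (normal-quantile monotonicity)
  l32 <- line_from_upper_ci(f, alpha = 0.32)
  expect_equal(l32$intercept, 11 + qnorm(0.84) * 0.2)
  expect_lt(l32$intercept, l$intercept)

  f_na <- fake_lme_fit(11, -1.3, NA_real_)
  expect_error(line_from_upper_ci(f_na), "bootstrap")
})

test_that("frontier line passes the fitted boundary through unchanged", {
  f <- structure(list(beta0 = 11.7, beta1 = -1.33, sigma_u = 0.2,
                      plot_effects = NULL), class = "sfmm_fit")
  l <- line_from_frontier(f)
  expect_equal(l$intercept, 11.7)
  expect_equal(l$slope, -1.33)

  # on synthetic frontier data the estimated line bounds ~95% of points
  d <- simulate_sfr_plots(n_plots = 150, obs_per_plot = 2, beta = c(12, -1.5),
                          sigma_v = 0.04, sigma_u = 0.3, sd_w = 0.1, seed = 23)
  fit <- suppressWarnings(fit_sfmm(d, restarts = 2))
  lf <- line_from_frontier(fit)
  above <- mean(log(d$n_ha) > lf$intercept + lf$slope * log(d$dg_cm))
  expect_lt(above, 0.10)
})

test_that("attractor line formulas match forced values and the ODE", {
  l <- line_from_ode_params(0, 1, 2)
  expect_equal(l$slope, -2)
  expect_equal(l$intercept, log(2))
  expect_equal(line_from_ode_params(-3, 0.5, 2.5)$slope, -1)
  expect_error(line_from_ode_params(0, 1, 0.8), "beta2")
  expect_error(line_from_ode_params(0, -1.2, 2), "beta1")

  # late segments of long simulated trajectories land on the line
  pars <- random_ode_params(5, seed = 57)
  for (i in seq_len(nrow(pars))) {
    b <- as.numeric(pars[i, ])
    l <- line_from_ode_params(b[1], b[2], b[3])
    dg0 <- 10
    N0 <- 1.5 * exp(l$intercept + l$slope * log(dg0))
    A <- exp(b[1]) * (b[3] - 1) / (b[2] + 1)
    C <- N0^(1 - b[3])
    dg_max <- (1e4 * (C + A * dg0^(b[2] + 1)) / A)^(1 / (b[2] + 1))
    grid <- exp(seq(log(dg0), log(dg_max), length.out = 120))
    N <- simulate_trajectory(b, N0, grid)
    late <- grid >= exp(0.7 * log(dg_max) + 0.3 * log(dg0))
    cf <- coef(lm(log(N[late]) ~ log(grid[late])))
    expect_lt(abs(cf[2] - l$slope) / abs(l$slope), 0.01)
    expect_lt(abs(cf[1] - l$intercept) / abs(l$intercept), 0.01)
  }
})

test_that("trajectory line inverts the Reineke part", {
  l <- line_from_trajectory(c(7.2, -0.62))
  expect_equal(l$intercept, 7.2 / 0.62)
  expect_equal(l$slope, -1 / 0.62)
  # round trip
  a0 <- -l$intercept / l$slope * -1  # forward map back
  expect_equal(c(-l$intercept / l$slope, 1 / l$slope), c(7.2, -0.62))
  expect_equal(line_from_trajectory(c(5, -1))$slope, -1)
  expect_equal(line_from_trajectory(c(5, -1))$intercept, 5)
  expect_error(line_from_trajectory(c(5, 0)), "alpha1")
})

test_that("predicted maximum density evaluates the line and is monotone", {
  l <- selfthin:::new_thinning_line("S-P-LQMM", 12.257, -1.4742, "upper-CI")
  expect_equal(predict_nmax(l), exp(12.257 - 1.4742 * log(25.4)))
  expect_equal(predict_nmax(l, dbase = 1), exp(12.257))
  d <- c(15, 20, 25.4, 30, 40)
  expect_true(all(diff(predict_nmax(l, dbase = d)) < 0))
  # plot effects shift capacity multiplicatively
  expect_equal(predict_nmax(l, plot_effect = log(2)), 2 * predict_nmax(l))
})

test_that("scheffe comparison separates distant groups and letters adjacent ones", {
  set.seed(33)
  eq <- data.frame(strategy = rep(c("A", "B", "C"), each = 20),
                   sdi_max = rnorm(60, 1000, 50))
  cmp <- scheffe_compare(eq)
  expect_true(all(cmp$groups$letters == "a"))

  far <- data.frame(strategy = rep(c("A", "B"), each = 20),
                    sdi_max = c(rnorm(20, 1000, 20), rnorm(20, 1400, 20)))
  cmp2 <- scheffe_compare(far)
  expect_false(cmp2$groups$letters[1] == cmp2$groups$letters[2])

  const <- data.frame(strategy = rep(c("A", "B"), each = 5),
                      sdi_max = rep(c(1, 2), each = 5))
  expect_error(scheffe_compare(const), "variance")
  expect_error(scheffe_compare(eq[eq$strategy == "A", ]), ">= 2 strategies")
})

test_that("compact letter display handles chains and distinct groups", {
  cld <- selfthin:::cld_insert_absorb
  # no significant pairs: everything shares one letter
  expect_equal(unname(cld(c("x", "y"), data.frame(a = character(0),
                                                  b = character(0)))),
               c("a", "a"))
  # chain a > c with b overlapping both
  out <- cld(c("a", "b", "c"), data.frame(a = "a", b = "c"))
  expect_true(grepl("a", out["a"]) && !grepl("a", out["c"]))
  expect_equal(unname(nchar(out["b"])), 2L)   # b shares with both
  # all pairs significant: three distinct letters
  sig <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"))
  expect_equal(unname(nchar(cld(c("a", "b", "c"), sig))), c(1L, 1L, 1L))
})

test_that("capacity estimates use plot effects where strategies have them", {
  d <- simulate_lqmm_plots(n_plots = 40, obs_per_plot = 2, seed = 41)
  f <- fit_lqmm(d, tau = 0.95, restarts = 1)
  cap <- capacity_estimates(list("S-P-LQMM" = f))
  expect_equal(nrow(cap), 40L)
  line <- line_from_upper_ci(f)
  i <- match(cap$plot_id[1], f$plot_effects$plot_id)
  expect_equal(cap$sdi_max[1],
               predict_nmax(line, plot_effect = f$plot_effects$u0[i]))
})

test_that("bioclim screening ranks the driving variable first", {
  set.seed(52)
  n <- 80
  cov <- data.frame(plot_id = sprintf("p%03d", 1:n))
  for (v in paste0("bio", 1:19)) cov[[v]] <- rnorm(n)
  capacity <- data.frame(plot_id = cov$plot_id,
                         sdi_max = 1400 + 120 * cov$bio14 + rnorm(n, 0, 80))
  tab <- screen_bioclim(capacity, cov)
  expect_equal(tab$variable[1], "bio14")
  expect_equal(nrow(tab), 19L)
  # single candidate
  tab1 <- screen_bioclim(capacity, cov, candidates = "bio3")
  expect_equal(nrow(tab1), 1L)
  cov$bioK <- 1
  expect_warning(screen_bioclim(capacity, cov, candidates = c("bio1", "bioK")),
                 "constant")
})

test_that("capacity model recovers noise-free coefficients and the PBA optimum", {
  set.seed(61)
  n <- 120
  cov <- data.frame(plot_id = sprintf("p%03d", 1:n),
                    shannon = runif(n, 0.2, 1.8),
                    bio14 = runif(n, 20, 70),
                    pba_pct = runif(n, 40, 100))
  th <- c(400, 150, 6, 30, -0.3)   # vertex at 50% PBA
  mu <- th[1] + th[2] * cov$shannon + th[3] * cov$bio14 +
    th[4] * cov$pba_pct + th[5] * cov$pba_pct^2
  fit0 <- suppressWarnings(
    fit_capacity_model(data.frame(plot_id = cov$plot_id, sdi_max = mu), cov))
  expect_equal(unname(fit0$coefficients), th, tolerance = 1e-8)
  expect_equal(fit0$pba_optimum, 50, tolerance = 1e-6)
  expect_lt(fit0$rel_rmse, 1e-8)

  # aliased designs are reported
  cov2 <- cov; cov2$dup <- cov2$shannon
  expect_error(fit_capacity_model(
    data.frame(plot_id = cov$plot_id, sdi_max = mu), cov2,
    formula = sdi_max ~ shannon + dup + bio14), "aliased")
})

test_that("the quantile pipeline recovers the generating frontier end to end", {
  # network with non-binding density envelopes, so frontier gaps are
  # independent of dg; averaged over seeds the fitted tau = 0.95 line sits
  # within 0.15 (intercept) and 0.08 (slope) of the generating frontier
  est <- t(vapply(1:8, function(s) {
    sim <- simulate_network(simulation_config(
      n_plots = 200, prop_dynamic = 0, n_range_static = c(1, 1e7),
      seed = 8800 + s))
    f <- fit_lqmm(sim$plots, tau = 0.95, restarts = 2)
    c(f$beta0_tau, f$beta1_tau)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - 12.0), 0.15)
  expect_lt(abs(mean(est[, 2]) + 1.5), 0.08)
})

test_that("dynamic fits reproduce the attractor line of the generating ODE", {
  bstar <- c(log(1.5) - 12, 0.5, 2)
  lstar <- line_from_ode_params(bstar[1], bstar[2], bstar[3])
  # density route
  ser <- simulate_density_series(n_plots = 60, occasions = 4,
                                 ode_params = bstar, seed = 71)
  fd <- fit_density_model(build_transitions(ser, exclude_ingrowth = FALSE),
                          random_specs = "b0")
  ld <- line_from_ode_params(fd)
  expect_lt(abs(ld$slope - lstar$slope) / abs(lstar$slope), 0.05)
  # mortality-count route: the implied slope is a ratio of the two
  # exponents and carries ~10% sampling noise per dataset, so the 5%
  # agreement is checked on the average over replicates
  slopes <- vapply(1:6, function(s) {
    tr <- simulate_nb_transitions(n_transitions = 500, n_plots = 100,
                                  beta = bstar, theta = 2, sd_u0 = 0.1,
                                  seed = 70 + s)
    line_from_ode_params(fit_mortality_nbme(tr))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - lstar$slope) / abs(lstar$slope), 0.05)
})
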