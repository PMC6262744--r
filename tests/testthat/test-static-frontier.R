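test_that("noise-free Reineke data are fitted exactly", {
  set.seed(2)
  dg <- runif(60, 10, 45)
  d <- data.frame(plot_id = rep(sprintf("p%02d", 1:20), each = 3),
                  n_ha = exp(12 - 1.6 * log(dg)), dg_cm = dg)
  f <- suppressWarnings(fit_lme_reineke(d))
  expect_equal(f$beta0, 12, tolerance = 1e-8)
  expect_equal(f$beta1, -1.6, tolerance = 1e-8)
})

test_that("degenerate designs for the Reineke fit error or fall back", {
  d <- data.frame(plot_id = c("a", "b"), n_ha = c(1000, 900),
                  dg_cm = c(20, 20))
  expect_error(fit_lme_reineke(d), "distinct dg")
  # one observation per plot: random-slope model degenerates with a warning
  set.seed(4)
  dg <- runif(40, 10, 45)
  one <- data.frame(plot_id = sprintf("p%02d", 1:40),
                    n_ha = exp(11.5 - 1.4 * log(dg) + rnorm(40, 0, 0.2)),
                    dg_cm = dg)
  expect_warning(f <- fit_lme_reineke(one), "random intercept")
  expect_equal(f$random, "intercept")
})

test_that("Reineke mixed model recovers its generating parameters", {
  R <- 25
  est <- t(vapply(seq_len(R), function(s) {
    d <- simulate_reineke_plots(n_plots = 120, obs_per_plot = 3,
                                beta = c(12, -1.5), sd_u0 = 0.3, sd_u1 = 0.08,
                                sd_e = 0.08, seed = 1000 + s)
    f <- suppressWarnings(fit_lme_reineke(d))
    c(b0 = f$beta0, b1 = f$beta1, s_e = sqrt(f$var_e))
  }, numeric(3)))
  expect_recovers(est, c(12, -1.5, 0.08), "S-P-LME")
})

test_that("lqmm with zero variance equals the pinball-loss oracle", {
  for (s in 1:3) {
    set.seed(300 + s)
    x <- runif(50, 2.3, 3.8)
    y <- 12 - 1.5 * x + rnorm(50, 0, 0.3)
    d <- data.frame(plot_id = sprintf("p%02d", 1:50),
                    n_ha = exp(y), dg_cm = exp(x))
    f <- fit_lqmm(d, tau = 0.5, var_u0 = 0)
    o <- pinball_pairs_oracle(y, x, 0.5)
    expect_lt(max(abs(c(f$beta0_tau, f$beta1_tau) - o$coef)), 1e-4)
  }
})

test_that("lqmm estimates are invariant to row duplication and relabeling", {
  d <- simulate_lqmm_plots(n_plots = 40, obs_per_plot = 2, seed = 6)
  f1 <- fit_lqmm(d, tau = 0.95, restarts = 2)
  # duplicated dataset: each plot appears twice under fresh labels
  d2 <- rbind(d, transform(d, plot_id = paste0(plot_id, "_dup")))
  f2 <- fit_lqmm(d2, tau = 0.95, restarts = 2)
  expect_equal(c(f1$beta0_tau, f1$beta1_tau),
               c(f2$beta0_tau, f2$beta1_tau), tolerance = 1e-3)
  # relabeling plots leaves the fit unchanged
  d3 <- d
  d3$plot_id <- factor(d3$plot_id,
                       labels = rev(sprintf("q%02d", seq_along(unique(d3$plot_id)))))
  f3 <- fit_lqmm(d3, tau = 0.95, restarts = 2)
  expect_equal(c(f1$beta0_tau, f1$beta1_tau),
               c(f3$beta0_tau, f3$beta1_tau), tolerance = 1e-6)
})

test_that("quantile selection returns a candidate minimizing the variance sum", {
  d <- simulate_lqmm_plots(n_plots = 60, obs_per_plot = 2, seed = 9)
  sel <- select_quantile(d, taus = c(0.90, 0.95), restarts = 1)
  expect_true(sel$tau %in% c(0.90, 0.95))
  expect_equal(nrow(sel$table), 2L)
  expect_equal(sel$table$var_sum[sel$table$tau == sel$tau],
               min(sel$table$var_sum))
  sel1 <- select_quantile(d, taus = 0.95, restarts = 1)
  expect_equal(sel1$tau, 0.95)
})

test_that("the composed-error frontier density integrates to one", {
  for (p in list(c(0.5, 0.3), c(0.2, 1.0), c(1.0, 0.05))) {
    f <- function(e) exp(selfthin:::sfr_logdens(e, p[1], p[2]))
    expect_equal(integrate(f, -Inf, Inf, rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)
  }
})

test_that("frontier fit collapses to OLS without inefficiency signal", {
  set.seed(12)
  dg <- runif(150, 10, 45)
  y <- 11.5 - 1.3 * log(dg) + rnorm(150, 0, 0.15)
  d <- data.frame(plot_id = sprintf("p%03d", 1:150), n_ha = exp(y), dg_cm = dg)
  f <- suppressWarnings(fit_sfmm(d, restarts = 2))
  ols <- lm(y ~ log(dg))
  # with no inefficiency in the data the composed model collapses towards
  # the Gaussian one: the implied mean line (frontier lowered by
  # E[U] = sigma_u * sqrt(2/pi)) matches OLS and sigma_u stays small
  expect_lt(f$sigma_u, 0.15)
  expect_lt(abs(f$beta1 - coef(ols)[2]), 0.02)
  expect_lt(abs((f$beta0 - f$sigma_u * sqrt(2 / pi)) - coef(ols)[1]), 0.02)
  # nesting: the optimized likelihood is at least the sigma_u = 0 value
  X <- cbind(1, log(dg)); gi <- factor(d$plot_id)
  gh <- selfthin:::gh_rule(15)
  ll0 <- -selfthin:::sfr_nll(c(coef(ols), log(sd(residuals(ols))),
                               log(1e-8), log(1e-8)), y, X, gi, gh)
  expect_gte(f$loglik, ll0 - 1e-3)
})

test_that("frontier fit recovers generating parameters", {
  R <- 12
  est <- t(vapply(seq_len(R), function(s) {
    d <- simulate_sfr_plots(n_plots = 100, obs_per_plot = 3,
                            beta = c(12, -1.5), sigma_v = 0.05,
                            sigma_u = 0.25, sd_w = 0.15, seed = 2000 + s)
    f <- suppressWarnings(fit_sfmm(d, restarts = 2))
    c(b0 = f$beta0, b1 = f$beta1, su = f$sigma_u)
  }, numeric(3)))
  expect_recovers(est, c(12, -1.5, 0.25), "S-P-SFMM")
})

test_that("quadrature and simulated ML agree on the frontier fit", {
  d <- simulate_sfr_plots(n_plots = 80, obs_per_plot = 2, seed = 17)
  fq <- suppressWarnings(fit_sfmm(d, restarts = 1))
  fs <- suppressWarnings(fit_sfmm(d, method = "sml", restarts = 1))
  expect_equal(c(fq$beta0, fq$beta1), c(fs$beta0, fs$beta1), tolerance = 0.02)
})
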