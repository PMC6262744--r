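test_that("transition building pairs consecutive occasions and filters", {
  pl <- data.frame(plot_id = rep("a", 3), occasion = 0:2,
                   n_ha = c(2000, 1800, 1500), dg_cm = c(12, 15, 19))
  tr <- build_transitions(pl)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$n0, c(2000, 1800))
  expect_equal(tr$delta_dg, c(3, 4))

  # ingrowth transitions are excluded and counted
  pl2 <- rbind(pl, data.frame(plot_id = "b", occasion = 0:2,
                              n_ha = c(1000, 1100, 900), dg_cm = c(10, 12, 14)))
  tr2 <- build_transitions(pl2)
  expect_equal(unname(attr(tr2, "excluded")["ingrowth"]), 1L)
  expect_equal(nrow(tr2), 3L)

  # non-increasing dg transitions are excluded and counted
  pl3 <- data.frame(plot_id = "c", occasion = 0:1, n_ha = c(900, 800),
                    dg_cm = c(15, 15))
  expect_warning(tr3 <- build_transitions(pl3), "no usable")
  expect_equal(unname(attr(tr3, "excluded")["dg"]), 1L)
})

test_that("noise-free density transitions are recovered exactly", {
  truth <- c(log(1e-5), 1, 2)
  set.seed(10)
  n0 <- runif(30, 800, 3000); dg0 <- runif(30, 10, 20)
  dg1 <- dg0 + runif(30, 2, 6)
  n1 <- vapply(1:30, function(i)
    simulate_trajectory(truth, n0[i], c(dg0[i], dg1[i]))[2], numeric(1))
  tr <- data.frame(plot_id = sprintf("p%02d", 1:30), n0 = n0, n1 = n1,
                   dg0 = dg0, dg1 = dg1, delta_n = n0 - n1,
                   delta_dg = dg1 - dg0, area_m2 = 10000)
  f <- fit_density_model(tr, random_specs = "none")
  expect_equal(unname(f$beta), truth, tolerance = 1e-6)
  expect_equal(nrow(f$comparison), 1L)
})

test_that("the density objective is locally optimal at the truth on clean data", {
  truth <- c(log(1e-5), 1, 2)
  set.seed(11)
  n0 <- runif(40, 800, 3000); dg0 <- runif(40, 10, 20)
  dg1 <- dg0 + runif(40, 2, 6)
  n1 <- vapply(1:40, function(i)
    simulate_trajectory(truth, n0[i], c(dg0[i], dg1[i]))[2], numeric(1))
  sse <- function(b) sum((log(n1) -
                            selfthin:::dens_model(n0, dg0, dg1, b[1], b[2], b[3]))^2)
  s0 <- sse(truth)
  set.seed(12)
  for (r in 1:20)
    expect_gte(sse(truth + rnorm(3, 0, 0.05)), s0)
})

test_that("density model with plot effects recovers parameters", {
  truth <- c(log(1.5) - 12, 0.5, 2)
  R <- 10
  est <- t(vapply(seq_len(R), function(s) {
    ser <- simulate_density_series(n_plots = 40, occasions = 4, seed = 4000 + s)
    tr <- build_transitions(ser)
    f <- fit_density_model(tr, random_specs = "b0")
    unname(f$beta)
  }, numeric(3)))
  colnames(est) <- c("b0", "b1", "b2")
  expect_recovers(est, truth, "D-P-LME")
})

test_that("mortality model wiring honours link, offsets and dispersion", {
  tr <- simulate_nb_transitions(n_transitions = 600, n_plots = 120,
                                beta = c(-10.5, 1, 1.4), theta = 2,
                                sd_u0 = 0.2, seed = 5)
  f <- fit_mortality_nbme(tr)
  # predicted mean at reference covariates equals the fitted link by hand
  mu_hat <- predict(f$model,
                    newdata = data.frame(plot_id = NA, l_dg0 = log(20),
                                         l_n0 = log(1000), off = log(2)),
                    type = "response", allow.new.levels = TRUE)
  by_hand <- exp(f$beta[1] + f$beta[2] * log(20) + f$beta[3] * log(1000) + log(2))
  expect_equal(unname(mu_hat), unname(by_hand), tolerance = 1e-8)
  expect_gt(f$theta, 0)
  expect_equal(unname(f$beta), c(-10.5, 1, 1.4), tolerance = 0.25)

  z <- tr; z$deaths <- 0L
  expect_error(fit_mortality_nbme(z), "no mortality")
})

test_that("negative binomial fit approaches Poisson on Poisson data", {
  set.seed(19)
  tr <- simulate_nb_transitions(n_transitions = 400, n_plots = 80,
                                beta = c(-10.5, 1, 1.4), theta = 1e9,
                                sd_u0 = 0.15, seed = 19)
  f <- suppressWarnings(fit_mortality_nbme(tr))
  pois <- glmmTMB::glmmTMB(deaths ~ l_dg0 + l_n0 + offset(off) + (1 | plot_id),
                           family = stats::poisson,
                           data = transform(tr, l_dg0 = log(dg0), l_n0 = log(n0),
                                            off = log(delta_dg)))
  expect_gt(f$theta, 50)
  expect_equal(unname(f$beta),
               unname(summary(pois)$coefficients$cond[, 1]), tolerance = 1e-2)
})

test_that("trajectory model is exact on noise-free data and anchored", {
  alpha <- c(7.2, -0.62, 0.05, 1.5)
  hs <- simulate_hann_series(n_plots = 30, occasions = 4, sigma_e = 0, seed = 3)
  f <- suppressWarnings(fit_trajectory_nlme(hs, random = FALSE))
  est <- f$alpha; est[3] <- abs(est[3])   # alpha2 enters squared
  expect_equal(unname(est), alpha, tolerance = 1e-5)

  # anchoring: at N = N1st the exponential factor is one, so the deviation
  # below the Reineke part equals (a0 a2)^2 / gap
  lnN1 <- log(3000); ldg1 <- alpha[1] + alpha[2] * lnN1 - 0.3
  dev <- (alpha[1] + alpha[2] * lnN1) -
    selfthin:::hann_curve(alpha, lnN1, lnN1, ldg1)
  expect_equal(dev, (alpha[1] * alpha[3])^2 / 0.3)

  # alpha2 = 0 degenerates to the straight Reineke line
  a0 <- c(7.2, -0.62, 0, 1.5)
  lnN <- seq(log(1500), log(3000), length.out = 5)
  expect_equal(selfthin:::hann_curve(a0, lnN, log(3000), ldg1),
               7.2 - 0.62 * lnN)
})

test_that("trajectory fit recovers parameters and stays monotone", {
  truth <- c(7.2, -0.62, 0.05, 1.5)
  R <- 12
  est <- t(vapply(seq_len(R), function(s) {
    hs <- simulate_hann_series(n_plots = 40, occasions = 5,
                               sigma_e = 0.015, seed = 5000 + s)
    f <- suppressWarnings(fit_trajectory_nlme(hs))
    a <- unname(f$alpha); a[3] <- abs(a[3]); a
  }, numeric(4)))
  colnames(est) <- paste0("a", 0:3)
  expect_recovers(est, truth, "D-P-NLME")
  # fitted curves predict larger dg at lower density
  a <- colMeans(est)
  lnN <- seq(log(4000), log(800), length.out = 20)
  pred <- selfthin:::hann_curve(a, lnN, log(4000),
                                a[1] + a[2] * log(4000) - 0.3)
  expect_true(all(diff(pred) > 0))
})
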