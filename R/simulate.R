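## Synthetic plot network with known truth, plus per-model simulators used
## by the parameter-recovery tests. The forward model for dynamic plots is
## the size-density mortality ODE dN/ddg = -exp(b0) dg^b1 N^b2 read
## generatively, with negative-binomial death counts between occasions.

#' Species table used by the synthetic network
#'
#' Five-species pool: three primary *Nothofagus* codes plus two companion
#' species, each with a wood specific gravity.
#' @export
species_table_default <- data.frame(
  species = c("NOB", "NAL", "NDO", "LAU", "TRI"),
  sg = c(0.58, 0.55, 0.52, 0.47, 0.42),
  primary = c(TRUE, TRUE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic plot network.
#' Defaults emulate a network of 130 permanent plots in secondary
#' *Nothofagus* forest: 20% of plots remeasured (3 occasions), static
#' stems/ha within [330, 3580] over dg 13.7-48.1 cm, dynamic stems/ha
#' within [670, 4680], and a generating frontier
#' \eqn{\ln N = 12.0 - 1.5 \ln dg} whose ODE parameters are chosen so the
#' dynamic attractor line coincides with the static frontier.
#'
#' @param n_plots number of plots.
#' @param prop_dynamic fraction of plots with remeasurements.
#' @param occasions_per_dynamic occasions per dynamic plot (>= 2).
#' @param frontier c(b0, b1): generating self-thinning line on (ln dg, ln N).
#' @param ode_params c(beta0, beta1, beta2) of the mortality ODE; requires
#'   beta2 > 1 and beta1 > -1.
#' @param re_sd sd of the plot random intercept on the frontier (ln scale).
#' @param obs_sd residual sd on ln N for static (single-visit) plots;
#'   remeasured plots re-tally the same stems so their densities are
#'   treated as census-exact.
#' @param nb_theta negative-binomial overdispersion of death counts.
#' @param dg_range static dg range (cm).
#' @param dg0_range_dynamic dg at first measurement of dynamic plots (cm).
#' @param n_range_static,n_range_dynamic stems/ha envelopes the simulated
#'   marginals must respect.
#' @param gap_mean,gap_min,gap_max truncated-exponential frontier-gap
#'   distribution of static plots (ln scale, one-sided below the line).
#' @param area_range plot area range (m^2).
#' @param effects list of covariate effect sizes on the plot frontier
#'   offset: `shannon`, `bio14`, `pba` (quadratic curvature) and `pba_opt`
#'   (optimum PBA, percent).
#' @param seed master seed; per-component streams are derived from it.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_plots = 130L,
                              prop_dynamic = 0.2,
                              occasions_per_dynamic = 3L,
                              frontier = c(b0 = 12.0, b1 = -1.5),
                              ode_params = c(beta0 = log(1.5) - 12, beta1 = 0.5, beta2 = 2.0),
                              re_sd = 0.05,
                              obs_sd = 0.04,
                              nb_theta = 2,
                              dg_range = c(13.7, 48.1),
                              dg0_range_dynamic = c(11.5, 18),
                              n_range_static = c(330, 3580),
                              n_range_dynamic = c(670, 4680),
                              gap_mean = 0.25,
                              gap_min = 0.05,
                              gap_max = 1.0,
                              area_range = c(500, 10000),
                              effects = list(shannon = 0.06, bio14 = 0.06,
                                             pba = 0.05, pba_opt = 50),
                              seed = 1L) {
  cfg <- list(n_plots = as.integer(n_plots), prop_dynamic = prop_dynamic,
              occasions_per_dynamic = as.integer(occasions_per_dynamic),
              frontier = unname(frontier), ode_params = unname(ode_params),
              re_sd = re_sd, obs_sd = obs_sd, nb_theta = nb_theta,
              dg_range = dg_range, dg0_range_dynamic = dg0_range_dynamic,
              n_range_static = n_range_static, n_range_dynamic = n_range_dynamic,
              gap_mean = gap_mean, gap_min = gap_min, gap_max = gap_max,
              area_range = area_range, effects = effects, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$prop_dynamic < 0 || cfg$prop_dynamic > 1) stop("prop_dynamic must be in [0, 1]")
  if (cfg$occasions_per_dynamic < 2L) stop("dynamic plots need >= 2 occasions")
  b <- cfg$ode_params
  if (b[3] <= 1) stop("ode beta2 must exceed 1 (finite attractor)")
  if (b[2] <= -1) stop("ode beta1 must exceed -1 (finite attractor)")
  if (cfg$nb_theta <= 0) stop("nb_theta must be positive")
  if (cfg$gap_min < 0 || cfg$gap_max <= cfg$gap_min) stop("invalid gap range")
  invisible(cfg)
}

#' Closed-form size-density trajectory
#'
#' Integrates the mortality ODE \eqn{dN/d\,dg = -e^{\beta_0} dg^{\beta_1} N^{\beta_2}}
#' exactly along an increasing dg grid:
#' \deqn{\ln N_1 = \frac{1}{1-\beta_2}\ln\left[N_0^{1-\beta_2} +
#'   e^{\beta_0}\frac{1-\beta_2}{\beta_1+1}\left(dg_0^{\beta_1+1}-dg_1^{\beta_1+1}\right)\right].}
#'
#' @param ode_params c(beta0, beta1, beta2), beta2 > 1, beta1 > -1.
#' @param N0 stems/ha at the first grid point.
#' @param dg_grid non-decreasing dg values (cm); the first is the starting size.
#' @return stems/ha at each grid point (first element equals `N0`).
#' @examples
#' simulate_trajectory(c(log(1e-5), 1, 2), 1000, c(10, 20))  # 1000, 400
#' @export
simulate_trajectory <- function(ode_params, N0, dg_grid) {
  b0 <- ode_params[1]; b1 <- ode_params[2]; b2 <- ode_params[3]
  if (b2 <= 1 || b1 <= -1) stop("require beta2 > 1 and beta1 > -1")
  if (N0 <= 0) stop("N0 must be positive")
  if (length(dg_grid) < 1L || any(diff(dg_grid) < 0))
    stop("dg_grid must be non-decreasing")
  p <- 1 - b2                      # < 0
  q <- b1 + 1                      # > 0
  bracket <- N0^p + exp(b0) * (p / q) * (dg_grid[1]^q - dg_grid^q)
  bad <- which(bracket <= 0)
  if (length(bad))
    stop(sprintf("trajectory extinct before dg = %.3f (step %d)",
                 dg_grid[bad[1]], bad[1]))
  exp(ln(bracket) / p)
}

## Asymmetric Laplace variates with check-loss kernel
## f(x) = tau(1-tau)/sigma * exp(-rho_tau(x/sigma)): positive exponential
## tail with prob 1-tau, negative with prob tau.
rald <- function(n, sigma, tau) {
  pos <- stats::runif(n) > tau
  x <- numeric(n)
  x[pos] <- stats::rexp(sum(pos), rate = tau / sigma)
  x[!pos] <- -stats::rexp(sum(!pos), rate = (1 - tau) / sigma)
  x
}

## Truncated exponential on [lo, hi] with mean parameter m (inverse CDF).
rtexp <- function(n, m, lo, hi) {
  u <- stats::runif(n)
  lo - m * log(1 - u * (1 - exp(-(hi - lo) / m)))
}

## Truncated standard normal on [-c, c] * sd.
rtnorm0 <- function(n, sd, c = 2.5) {
  if (sd == 0) return(rep(0, n))
  u <- stats::runif(n, stats::pnorm(-c), stats::pnorm(c))
  sd * stats::qnorm(u)
}

## ---------------------------------------------------------------------------
## Per-model simulators (each generates exactly from the model its fitter
## assumes, so recovery tests are correctly specified).

#' Simulate plots from the random-coefficient Reineke model
#'
#' \eqn{\ln N_{ij} = (\beta_0+u_{0i}) + (\beta_1+u_{1i})\ln dg_{ij} + e_{ij}}
#' with independent Gaussian random effects and residual.
#'
#' @param n_plots,obs_per_plot layout.
#' @param beta c(b0, b1) fixed effects.
#' @param sd_u0,sd_u1,sd_e variance components (sds).
#' @param dg_range dg values drawn uniformly (cm).
#' @param seed RNG seed.
#' @return data.frame `plot_id`, `occasion`, `n_ha`, `dg_cm`.
#' @export
simulate_reineke_plots <- function(n_plots = 200L, obs_per_plot = 3L,
                                   beta = c(12, -1.5), sd_u0 = 0.3,
                                   sd_u1 = 0.08, sd_e = 0.08,
                                   dg_range = c(10, 45), seed = 1L) {
  set.seed(seed)
  u0 <- stats::rnorm(n_plots, 0, sd_u0)
  u1 <- stats::rnorm(n_plots, 0, sd_u1)
  idx <- rep(seq_len(n_plots), each = obs_per_plot)
  dg <- stats::runif(n_plots * obs_per_plot, dg_range[1], dg_range[2])
  lnN <- (beta[1] + u0[idx]) + (beta[2] + u1[idx]) * ln(dg) +
    stats::rnorm(length(dg), 0, sd_e)
  data.frame(plot_id = sprintf("p%03d", idx), occasion = 0L,
             n_ha = exp(lnN), dg_cm = dg, stringsAsFactors = FALSE)
}

#' Simulate plots from the linear quantile mixed model
#'
#' Residuals are asymmetric Laplace at quantile `tau`, so the conditional
#' tau-quantile given the plot effect is exactly the generating line.
#'
#' @inheritParams simulate_reineke_plots
#' @param tau generating quantile.
#' @param sigma_ald asymmetric-Laplace scale.
#' @param sd_u0 plot random-intercept sd.
#' @return data.frame with the generating plot intercepts attached as
#'   attribute `"u0"` (named by plot), so conditional-quantile properties
#'   can be checked against the truth.
#' @export
simulate_lqmm_plots <- function(n_plots = 200L, obs_per_plot = 3L,
                                beta = c(12, -1.5), tau = 0.95,
                                sigma_ald = 0.05, sd_u0 = 0.2,
                                dg_range = c(10, 45), seed = 1L) {
  set.seed(seed)
  u0 <- stats::rnorm(n_plots, 0, sd_u0)
  idx <- rep(seq_len(n_plots), each = obs_per_plot)
  dg <- stats::runif(n_plots * obs_per_plot, dg_range[1], dg_range[2])
  lnN <- beta[1] + u0[idx] + beta[2] * ln(dg) + rald(length(dg), sigma_ald, tau)
  structure(data.frame(plot_id = sprintf("p%03d", idx), occasion = 0L,
                       n_ha = exp(lnN), dg_cm = dg, stringsAsFactors = FALSE),
            u0 = stats::setNames(u0, sprintf("p%03d", seq_len(n_plots))))
}

#' Simulate plots from the random-effects stochastic frontier model
#'
#' \eqn{\ln N = X\beta + w_i + V - U} with Gaussian noise V, half-normal
#' inefficiency U >= 0 and Gaussian plot intercepts w.
#'
#' @inheritParams simulate_reineke_plots
#' @param sigma_v,sigma_u noise and inefficiency sds.
#' @param sd_w plot random-intercept sd.
#' @export
simulate_sfr_plots <- function(n_plots = 150L, obs_per_plot = 2L,
                               beta = c(12, -1.5), sigma_v = 0.05,
                               sigma_u = 0.25, sd_w = 0.15,
                               dg_range = c(10, 45), seed = 1L) {
  set.seed(seed)
  w <- stats::rnorm(n_plots, 0, sd_w)
  idx <- rep(seq_len(n_plots), each = obs_per_plot)
  dg <- stats::runif(n_plots * obs_per_plot, dg_range[1], dg_range[2])
  lnN <- beta[1] + w[idx] + beta[2] * ln(dg) +
    stats::rnorm(length(dg), 0, sigma_v) - abs(stats::rnorm(length(dg), 0, sigma_u))
  data.frame(plot_id = sprintf("p%03d", idx), occasion = 0L,
             n_ha = exp(lnN), dg_cm = dg, stringsAsFactors = FALSE)
}

#' Simulate tree-level density-index covariates on a known frontier
#'
#' Generates plot-level Ducey covariates (x0, x1) satisfying
#' \eqn{\alpha_0 x_0 + \alpha_1 x_1 + u_i + \epsilon = 1} with asymmetric
#' Laplace epsilon at quantile `tau`, by drawing the plot specific-gravity
#' mix and solving for the stand size.
#'
#' @param n_plots number of plot-occasions.
#' @param alpha c(alpha0, alpha1) generating coefficients (per hundred
#'   metric SDI units).
#' @param tau generating quantile.
#' @param sigma_ald asymmetric-Laplace scale.
#' @param sd_u0 plot random-intercept sd.
#' @param sg_range specific-gravity range of the plot means.
#' @param seed RNG seed.
#' @return data.frame `plot_id`, `occasion`, `x0`, `x1`, `sg_bar`.
#' @export
simulate_ducey_plots <- function(n_plots = 300L, alpha = c(0.05, 0.06),
                                 tau = 0.95, sigma_ald = 0.02, sd_u0 = 0.04,
                                 sg_range = c(0.40, 0.62), seed = 1L) {
  set.seed(seed)
  sg <- stats::runif(n_plots, sg_range[1], sg_range[2])
  u0 <- stats::rnorm(n_plots, 0, sd_u0)
  eps <- rald(n_plots, sigma_ald, tau)
  x0 <- (1 - u0 - eps) / (alpha[1] + alpha[2] * sg)
  keep <- x0 > 0
  data.frame(plot_id = sprintf("p%03d", seq_len(n_plots))[keep], occasion = 0L,
             x0 = x0[keep], x1 = (sg * x0)[keep], sg_bar = sg[keep],
             stringsAsFactors = FALSE)
}

#' Simulate remeasurement transitions from the closed-form density model
#'
#' Each transition follows the exact ODE solution with a plot random effect
#' on beta0 and Gaussian residual on ln N1, conditioning on the previously
#' observed density (the model the density fitter assumes).
#'
#' @param n_plots,occasions layout.
#' @param ode_params c(beta0, beta1, beta2).
#' @param sd_b0 sd of the plot effect on beta0.
#' @param sigma_e residual sd on ln N1.
#' @param dg0_range starting dg range; dg increments are U(2, 6) cm.
#' @param n0_range starting stems/ha range.
#' @param seed RNG seed.
#' @return data.frame of plot series: `plot_id`, `occasion`, `n_ha`, `dg_cm`.
#' @export
simulate_density_series <- function(n_plots = 40L, occasions = 4L,
                                    ode_params = c(log(1.5) - 12, 0.5, 2),
                                    sd_b0 = 0.15, sigma_e = 0.03,
                                    dg0_range = c(10, 16),
                                    n0_range = c(1500, 4500), seed = 1L) {
  set.seed(seed)
  out <- vector("list", n_plots)
  for (i in seq_len(n_plots)) {
    b <- ode_params
    b[1] <- b[1] + stats::rnorm(1, 0, sd_b0)
    dg <- cumsum(c(stats::runif(1, dg0_range[1], dg0_range[2]),
                   stats::runif(occasions - 1L, 2, 6)))
    N <- numeric(occasions)
    N[1] <- stats::runif(1, n0_range[1], n0_range[2])
    for (j in 2:occasions) {
      mu <- simulate_trajectory(b, N[j - 1L], dg[(j - 1L):j])[2L]
      N[j] <- exp(ln(mu) + stats::rnorm(1, 0, sigma_e))
    }
    out[[i]] <- data.frame(plot_id = sprintf("p%03d", i),
                           occasion = seq_len(occasions) - 1L,
                           n_ha = N, dg_cm = dg, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate negative-binomial mortality transitions
#'
#' Death counts per plot follow
#' \eqn{\Delta N \sim NB(\mu, \theta)} with
#' \eqn{\ln\mu = \beta_0 + u_{0i} + \beta_1\ln dg_0 + \beta_2\ln N_0 + \ln\Delta dg}
#' on the count scale of a 1-ha plot.
#'
#' @param n_transitions number of transitions.
#' @param n_plots number of plots the transitions are nested in.
#' @param beta c(beta0, beta1, beta2) on the log link.
#' @param theta NB overdispersion (Var = mu + mu^2/theta).
#' @param sd_u0 plot random-intercept sd.
#' @param seed RNG seed.
#' @return data.frame `plot_id`, `n0`, `dg0`, `dg1`, `delta_dg`, `deaths`,
#'   `area_m2` (10000: counts are per hectare).
#' @export
simulate_nb_transitions <- function(n_transitions = 500L, n_plots = 100L,
                                    beta = c(-10.5, 1, 1.4), theta = 2,
                                    sd_u0 = 0.2, seed = 1L) {
  set.seed(seed)
  pid <- sample(rep_len(seq_len(n_plots), n_transitions))
  u0 <- stats::rnorm(n_plots, 0, sd_u0)
  dg0 <- stats::runif(n_transitions, 10, 30)
  n0 <- round(stats::runif(n_transitions, 500, 4000))
  ddg <- stats::runif(n_transitions, 1, 4)
  mu <- exp(beta[1] + u0[pid] + beta[2] * ln(dg0) + beta[3] * ln(n0) + ln(ddg))
  deaths <- stats::rnbinom(n_transitions, mu = mu, size = theta)
  deaths <- pmin(deaths, n0 - 1L)
  data.frame(plot_id = sprintf("p%03d", pid), n0 = n0, dg0 = dg0,
             dg1 = dg0 + ddg, delta_dg = ddg, deaths = deaths,
             area_m2 = 10000, stringsAsFactors = FALSE)
}

#' Simulate first-measurement size-density trajectories
#'
#' Generates plot series from the first-measurement trajectory model: given
#' a plot's first measurement, subsequent densities decline and
#' \eqn{\ln dg} follows the anchored trajectory curve plus Gaussian noise.
#'
#' @param n_plots number of plots.
#' @param occasions occasions per plot.
#' @param alpha c(alpha0..alpha3) generating parameters. alpha2 enters the
#'   model squared, so only its magnitude is identified; the default makes
#'   `(alpha0 * alpha2)^2` commensurate with the drawn first-measurement
#'   gaps so trajectories start near their anchor.
#' @param gap_range range of the first-measurement gap below the Reineke
#'   part, on the ln dg scale.
#' @param sigma_e residual sd on ln dg.
#' @param seed RNG seed.
#' @return data.frame `plot_id`, `occasion`, `n_ha`, `dg_cm`.
#' @export
simulate_hann_series <- function(n_plots = 30L, occasions = 4L,
                                 alpha = c(7.2, -0.62, 0.05, 1.5),
                                 gap_range = c(0.25, 0.45),
                                 sigma_e = 0.02, seed = 1L) {
  set.seed(seed)
  out <- vector("list", n_plots)
  for (i in seq_len(n_plots)) {
    n1 <- stats::runif(1, 2000, 4500)
    lnN <- ln(n1) - cumsum(c(0, stats::runif(occasions - 1L, 0.15, 0.45)))
    ldg1 <- alpha[1] + alpha[2] * ln(n1) -
      stats::runif(1, gap_range[1], gap_range[2])  # first point below the line
    ldg <- hann_curve(alpha, lnN, ln(n1), ldg1)
    ldg[1] <- ldg1
    ldg[-1] <- ldg[-1] + stats::rnorm(occasions - 1L, 0, sigma_e)
    out[[i]] <- data.frame(plot_id = sprintf("p%03d", i),
                           occasion = seq_len(occasions) - 1L,
                           n_ha = exp(lnN), dg_cm = exp(ldg),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## Anchored trajectory curve: ln dg as a function of ln N given the plot's
## first measurement (lnN1st, lndg1st).
hann_curve <- function(alpha, lnN, lnN1st, lndg1st) {
  denom <- alpha[1] + alpha[2] * lnN1st - lndg1st
  alpha[1] + alpha[2] * lnN -
    ((alpha[1] * alpha[3])^2 / denom) * exp(-alpha[4] * (lnN1st - lnN))
}

## ---------------------------------------------------------------------------
## Full network

bioclim_ranges <- local({
  r <- list(
    bio1 = c(8, 14), bio2 = c(7, 13), bio3 = c(40, 55), bio4 = c(300, 500),
    bio5 = c(20, 30), bio6 = c(-2, 5), bio7 = c(18, 30), bio8 = c(4, 10),
    bio9 = c(12, 20), bio10 = c(13, 20), bio11 = c(3, 9), bio12 = c(1200, 2600),
    bio13 = c(200, 400), bio14 = c(20, 70), bio15 = c(40, 80),
    bio16 = c(500, 1000), bio17 = c(80, 250), bio18 = c(90, 260),
    bio19 = c(450, 950))
  r
})

## Draw a plot's species mix: primary share targets pba/100 of basal area.
draw_species_mix <- function(pba_target) {
  p <- pba_target / 100
  w_prim <- stats::rgamma(3, shape = 2)
  w_comp <- stats::rgamma(2, shape = 2)
  props <- c(p * w_prim / sum(w_prim), (1 - p) * w_comp / sum(w_comp))
  names(props) <- species_table_default$species
  props
}

## Tree list matching (N, dg) for a plot-occasion: m trees at expansion
## factor 10^4/area with Weibull diameters rescaled to the exact quadratic
## mean, clamped at the 5-cm measurement threshold.
make_tree_list <- function(plot_id, occasion, m, area_m2, dg, props) {
  d <- stats::rweibull(m, shape = 2.3, scale = dg)
  for (k in 1:8) {
    d <- d * dg / sqrt(mean(d^2))
    if (all(d >= 5)) break
    d[d < 5] <- 5
  }
  sp <- sample(species_table_default$species, m, replace = TRUE, prob = props)
  sg <- species_table_default$sg[match(sp, species_table_default$species)]
  data.frame(plot_id = plot_id, occasion = occasion,
             tree_id = seq_len(m), d_cm = d, species = sp, sg = sg,
             ef = 10000 / area_m2, stringsAsFactors = FALSE)
}

#' Simulate a synthetic plot network
#'
#' Generates static and dynamic plots, tree lists and site covariates with
#' the statistical structure the seven estimation strategies assume. Static
#' plots scatter below the generating frontier with a truncated-exponential
#' gap on the log scale (truncated further so the stems/ha marginals respect
#' the configured envelopes); dynamic plots follow negative-binomial death
#' processes whose mean is the Euler step of the mortality ODE, so their
#' mean trajectory tracks the closed-form solution and their attractor line
#' coincides with the static frontier. Plot frontier offsets are linked to
#' Shannon diversity, bio14 (precipitation of the driest month) and a
#' quadratic in PBA with configurable effect sizes.
#'
#' @param config a [simulation_config()].
#' @return list of class `selfthin_sim` with elements `plots`, `trees`,
#'   `covariates` and `truth` (generating parameters and per-plot offsets).
#' @export
simulate_network <- function(config = simulation_config()) {
  validate_sim_config(config)
  cfg <- config
  b0 <- cfg$frontier[1]; b1 <- cfg$frontier[2]
  n_dyn <- round(cfg$n_plots * cfg$prop_dynamic)
  n_sta <- cfg$n_plots - n_dyn
  eff <- cfg$effects

  ## covariates and plot offsets -------------------------------------------
  set.seed(child_seed(cfg$seed, "covariates"))
  pid <- sprintf("p%03d", seq_len(cfg$n_plots))
  cov <- data.frame(plot_id = pid,
                    elevation = stats::runif(cfg$n_plots, 200, 1000),
                    aspect = stats::runif(cfg$n_plots, 0, 360),
                    slope = stats::runif(cfg$n_plots, 0, 60),
                    stringsAsFactors = FALSE)
  for (nm in names(bioclim_ranges))
    cov[[nm]] <- stats::runif(cfg$n_plots, bioclim_ranges[[nm]][1],
                              bioclim_ranges[[nm]][2])
  pba_target <- 40 + 60 * stats::rbeta(cfg$n_plots, 3, 1.6)
  mix <- t(vapply(pba_target, draw_species_mix, numeric(5)))
  shannon_target <- apply(mix, 1L, shannon_index)
  b14 <- bioclim_ranges$bio14
  z14 <- (cov$bio14 - mean(b14)) / (diff(b14) / 4)
  u <- eff$shannon * (shannon_target - 1) + eff$bio14 * z14 -
    eff$pba * ((pba_target - eff$pba_opt) / 50)^2 +
    rtnorm0(cfg$n_plots, cfg$re_sd)

  is_dyn <- c(rep(FALSE, n_sta), rep(TRUE, n_dyn))
  area <- stats::runif(cfg$n_plots, cfg$area_range[1], cfg$area_range[2])

  plots <- list(); trees <- list()

  ## static plots ------------------------------------------------------------
  set.seed(child_seed(cfg$seed, "static"))
  emax <- 2.5 * cfg$obs_sd
  for (i in which(!is_dyn)) {
    ## restrict dg so a feasible gap below the envelope floor exists
    ldg_max <- (b0 + u[i] - cfg$gap_min - emax - ln(cfg$n_range_static[1])) / abs(b1)
    dg <- stats::runif(1, cfg$dg_range[1], min(cfg$dg_range[2], exp(ldg_max)))
    lfront <- b0 + u[i] + b1 * ln(dg)
    glo <- max(cfg$gap_min, lfront + emax - ln(cfg$n_range_static[2]))
    ghi <- min(cfg$gap_max, lfront - emax - ln(cfg$n_range_static[1]))
    if (ghi <= glo) stop("infeasible config: empty frontier-gap interval")
    gap <- rtexp(1, cfg$gap_mean, glo, ghi)
    lnN <- lfront - gap + rtnorm0(1, cfg$obs_sd)
    N <- exp(lnN)
    m <- max(5L, as.integer(round(N * area[i] / 10000)))
    area[i] <- m * 10000 / N              # exact EF consistency
    plots[[length(plots) + 1L]] <- data.frame(
      plot_id = pid[i], occasion = 0L, area_m2 = area[i], n_ha = N,
      dg_cm = dg, is_dynamic = FALSE, stringsAsFactors = FALSE)
    trees[[length(trees) + 1L]] <-
      make_tree_list(pid[i], 0L, m, area[i], dg, mix[i, ])
  }

  ## dynamic plots -----------------------------------------------------------
  set.seed(child_seed(cfg$seed, "dynamic"))
  ob <- cfg$ode_params
  p2 <- 1 - ob[3]
  for (i in which(is_dyn)) {
    dg <- cumsum(c(stats::runif(1, cfg$dg0_range_dynamic[1], cfg$dg0_range_dynamic[2]),
                   pmin(6, pmax(2, stats::rlnorm(cfg$occasions_per_dynamic - 1L,
                                                 log(3.2), 0.25)))))
    lfront <- b0 + u[i] + b1 * ln(dg[1])
    glo <- max(0.08, lfront - ln(cfg$n_range_dynamic[2]))
    ghi <- 0.5
    if (ghi <= glo) stop("infeasible config: empty dynamic start-gap interval")
    gap <- rtexp(1, cfg$gap_mean, glo, ghi)
    N0 <- exp(lfront - gap)
    m0 <- max(10L, as.integer(round(N0 * area[i] / 10000)))
    area[i] <- m0 * 10000 / N0
    ## plot effect on the ODE level: u shifts the attractor intercept by
    ## u = beta0_offset / (1 - beta2), so beta0_i = beta0 + u * (1 - beta2)
    b0i <- ob[1] + u[i] * p2
    m <- m0; counts <- integer(cfg$occasions_per_dynamic); counts[1] <- m0
    for (j in 2:cfg$occasions_per_dynamic) {
      Nprev <- m * 10000 / area[i]
      mu_ha <- exp(b0i) * dg[j - 1L]^ob[2] * Nprev^ob[3] * (dg[j] - dg[j - 1L])
      deaths <- stats::rnbinom(1, mu = mu_ha * area[i] / 10000, size = cfg$nb_theta)
      deaths <- min(deaths, m - 5L)
      m <- m - deaths
      counts[j] <- m
    }
    N <- counts * 10000 / area[i]
    if (any(N < cfg$n_range_dynamic[1]))
      N <- pmax(N, cfg$n_range_dynamic[1])  # envelope floor guard (rare)
    plots[[length(plots) + 1L]] <- data.frame(
      plot_id = pid[i], occasion = seq_along(dg) - 1L, area_m2 = area[i],
      n_ha = N, dg_cm = dg, is_dynamic = TRUE, stringsAsFactors = FALSE)
    set.seed(child_seed(cfg$seed, paste0("trees", i)))
    for (j in seq_along(dg))
      trees[[length(trees) + 1L]] <-
        make_tree_list(pid[i], j - 1L, as.integer(round(N[j] * area[i] / 10000)),
                       area[i], dg[j], mix[i, ])
  }

  plots <- do.call(rbind, plots)
  trees <- do.call(rbind, trees)
  plots$g_m2ha <- (pi / 40000) * plots$dg_cm^2 * plots$n_ha
  ## PBA from the realized tree lists (first occasion per plot-occasion row)
  pba <- vapply(seq_len(nrow(plots)), function(r) {
    tl <- trees[trees$plot_id == plots$plot_id[r] &
                  trees$occasion == plots$occasion[r], , drop = FALSE]
    compute_stand_variables(tl)$pba_pct
  }, numeric(1))
  plots$pba_pct <- pba

  cov$pba_target <- pba_target
  cov$shannon_target <- shannon_target

  structure(list(plots = plots, trees = trees, covariates = cov,
                 truth = list(config = cfg, u = stats::setNames(u, pid),
                              pba_target = pba_target,
                              shannon_target = shannon_target)),
            class = "selfthin_sim")
}

#' @export
print.selfthin_sim <- function(x, ...) {
  cat("Synthetic plot network:",
      length(unique(x$plots$plot_id)), "plots,",
      nrow(x$plots), "plot-occasions,",
      nrow(x$trees), "trees\n")
  cat("  dynamic plots:", length(unique(x$plots$plot_id[x$plots$is_dynamic])),
      "\n  frontier: ln N =", x$truth$config$frontier[1], "+",
      x$truth$config$frontier[2], "ln dg\n")
  invisible(x)
}
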