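## Dynamic strategies on remeasured plots: closed-form density model
## (D-P-LME), negative-binomial mortality model (D-P-NBME) and the
## first-measurement trajectory model (D-P-NLME).

#' Build remeasurement transitions
#'
#' Pairs consecutive occasions within each plot. Transitions with apparent
#' ingrowth (N increasing) or non-increasing dg are excluded; counts of the
#' exclusions are attached as attribute `"excluded"`.
#'
#' @param plots plot table with `plot_id`, `occasion`, `n_ha`, `dg_cm`, and
#'   optionally `area_m2`.
#' @param exclude_ingrowth drop transitions with increasing N (default).
#'   Set `FALSE` when apparent increases are pure measurement noise and the
#'   downstream model accommodates them; excluding them then truncates the
#'   residual distribution and biases the density fit.
#' @return data.frame `plot_id`, `occasion0`, `occasion1`, `n0`, `n1`,
#'   `dg0`, `dg1`, `delta_n`, `delta_dg` (+ `area_m2`).
#' @export
build_transitions <- function(plots, exclude_ingrowth = TRUE) {
  has_area <- "area_m2" %in% names(plots)
  out <- list(); dropped_ingrowth <- 0L; dropped_dg <- 0L
  for (pid in unique(plots$plot_id)) {
    sub <- plots[plots$plot_id == pid, , drop = FALSE]
    if (nrow(sub) < 2L) next
    sub <- sub[order(sub$occasion), , drop = FALSE]
    for (j in seq_len(nrow(sub) - 1L)) {
      a <- sub[j, ]; b <- sub[j + 1L, ]
      if (b$dg_cm <= a$dg_cm) { dropped_dg <- dropped_dg + 1L; next }
      if (exclude_ingrowth && b$n_ha > a$n_ha) {
        dropped_ingrowth <- dropped_ingrowth + 1L; next
      }
      out[[length(out) + 1L]] <- data.frame(
        plot_id = pid, occasion0 = a$occasion, occasion1 = b$occasion,
        n0 = a$n_ha, n1 = b$n_ha, dg0 = a$dg_cm, dg1 = b$dg_cm,
        delta_n = a$n_ha - b$n_ha, delta_dg = b$dg_cm - a$dg_cm,
        area_m2 = if (has_area) a$area_m2 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    warning("no usable transitions")
    res <- data.frame(plot_id = character(0), occasion0 = integer(0),
                      occasion1 = integer(0), n0 = numeric(0), n1 = numeric(0),
                      dg0 = numeric(0), dg1 = numeric(0), delta_n = numeric(0),
                      delta_dg = numeric(0), area_m2 = numeric(0))
  } else res <- do.call(rbind, out)
  attr(res, "excluded") <- c(ingrowth = dropped_ingrowth, dg = dropped_dg)
  res
}

## Closed-form solution of the mortality ODE used as the nonlinear mean
## function; the bracket is clamped so that proposals implying extinction
## yield a penalized (finite) objective instead of a crash.
dens_model <- function(n0, dg0, dg1, b0, b1, b2) {
  p <- 1 - b2
  q <- b1 + 1
  br <- n0^p + exp(b0) * (p / q) * (dg0^q - dg1^q)
  log(pmax(br, 1e-12)) / p
}

density_start <- function(tr) {
  b1 <- 0.8; b2 <- 1.8
  rate <- pmax(tr$delta_n, 0.5) / (tr$dg0^b1 * tr$n0^b2 * tr$delta_dg)
  c(b0 = log(mean(rate)), b1 = b1, b2 = b2)
}

## Exact marginal ML for a single Gaussian random effect on one ODE
## parameter, integrated by Gauss-Hermite quadrature (the linearization
## used by approximate nonlinear-mixed fitters biases these estimates).
## theta = (b0, b1, b2, log sd_u, log sigma_e).
density_ml_lli <- function(theta, tr, spec, gi, gh) {
  sd_u <- exp(theta[4]); sig <- exp(theta[5])
  shift <- sqrt(2) * sd_u * gh$x
  L <- vapply(shift, function(s) {
    b <- theta[1:3]
    b[match(spec, c("b0", "b1", "b2"))] <- b[match(spec, c("b0", "b1", "b2"))] + s
    mu <- dens_model(tr$n0, tr$dg0, tr$dg1, b[1], b[2], b[3])
    stats::dnorm(tr$lnN1, mu, sig, log = TRUE)
  }, numeric(nrow(tr)))
  Gm <- rowsum(L, gi)
  logsumexp(sweep(Gm, 2L, log(gh$w), "+"))
}

density_ml_fit <- function(tr, spec, start, nodes = 15L) {
  gi <- factor(tr$plot_id)
  gh <- gh_rule(nodes)
  r0 <- tr$lnN1 - dens_model(tr$n0, tr$dg0, tr$dg1, start[1], start[2], start[3])
  th0 <- c(unname(start), log(max(stats::sd(r0), 0.02)),
           log(max(stats::sd(r0) * 0.8, 0.01)))
  nll <- function(th) -sum(density_ml_lli(th, tr, spec, gi, gh))
  o <- stats::optim(th0, nll, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-10))
  o <- stats::optim(o$par, nll, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 4000))
  th <- o$par
  V <- opg_covariance(function(t) density_ml_lli(t, tr, spec, gi, gh), th)
  se <- suppressWarnings(sqrt(diag(V)))
  ## posterior modes of the plot effect
  sd_u <- exp(th[4]); sig <- exp(th[5])
  modes <- vapply(levels(gi), function(l) {
    sub <- tr[gi == l, , drop = FALSE]
    f <- function(u) {
      b <- th[1:3]
      b[match(spec, c("b0", "b1", "b2"))] <- b[match(spec, c("b0", "b1", "b2"))] + u
      -sum(stats::dnorm(sub$lnN1,
                        dens_model(sub$n0, sub$dg0, sub$dg1, b[1], b[2], b[3]),
                        sig, log = TRUE)) + u^2 / (2 * sd_u^2)
    }
    stats::optimize(f, c(-6 * sd_u - 0.1, 6 * sd_u + 0.1))$minimum
  }, numeric(1))
  list(beta = th[1:3], se = se[1:3], sd_u = sd_u, sigma_e = sig,
       loglik = -o$value, modes = modes)
}

#' Fit the closed-form density model (D-P-LME)
#'
#' Nonlinear (mixed) maximum-likelihood fit of ln N1 via the exact solution
#' of \eqn{dN/d\,dg = -e^{\beta_0} dg^{\beta_1} N^{\beta_2}} with Gaussian
#' residual. Candidate random-effect placements are fitted and compared by
#' BIC; the best variant is returned together with the comparison table.
#'
#' @param transitions data.frame from [build_transitions()].
#' @param random_specs character subset of `c("b0", "b1", "b2", "all",
#'   "none")`; `"all"` places independent plot effects on every parameter,
#'   `"none"` is a fixed-effects nonlinear fit.
#' @param start optional named start values c(b0, b1, b2).
#' @return object of class `density_fit`: `beta` (b0, b1, b2), `se`,
#'   `random_effect_spec`, `re_sd` (named sds), `sigma_e`, `loglik`, `bic`,
#'   `comparison` table and `plot_effects`.
#' @export
fit_density_model <- function(transitions,
                              random_specs = c("b0", "b1", "b2", "all"),
                              start = NULL) {
  tr <- transitions
  if (nrow(tr) < 3L) stop("too few transitions")
  random_specs <- match.arg(random_specs, c("b0", "b1", "b2", "all", "none"),
                            several.ok = TRUE)
  tr$lnN1 <- ln(tr$n1)
  if (is.null(start)) start <- density_start(tr)
  ## the closed form is inlined (base functions only) because nlme
  ## evaluates the model away from the package namespace
  form <- lnN1 ~ log(pmax(n0^(1 - b2) + exp(b0) * ((1 - b2) / (b1 + 1)) *
                            (dg0^(b1 + 1) - dg1^(b1 + 1)), 1e-12)) / (1 - b2)
  ## fixed-effects start refinement
  fx <- tryCatch(
    minpack.lm::nlsLM(form, data = tr, start = as.list(start),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fx)) start <- stats::coef(fx)

  fits <- list(); rows <- list()
  for (spec in random_specs) {
    f <- tryCatch({
      if (spec == "none") {
        if (is.null(fx)) stop("fixed-effects fit failed")
        list(kind = "nls",
             beta = stats::coef(fx),
             se = summary(fx)$coefficients[, "Std. Error"],
             re_sd = numeric(0), sigma_e = summary(fx)$sigma,
             loglik = as.numeric(stats::logLik(fx)),
             k = attr(stats::logLik(fx), "df"), pe = NULL, model = fx)
      } else if (spec == "all") {
        ## three correlated-free plot effects: quadrature is impractical,
        ## use the linearized nonlinear mixed fit
        m <- nlme::nlme(form, fixed = b0 + b1 + b2 ~ 1,
                        random = nlme::pdDiag(b0 + b1 + b2 ~ 1),
                        groups = ~plot_id, data = tr, start = unname(start),
                        method = "ML",
                        control = nlme::nlmeControl(maxIter = 200,
                                                    pnlsMaxIter = 20,
                                                    msMaxIter = 200,
                                                    returnObject = TRUE))
        vc <- suppressWarnings(nlme::VarCorr(m))
        re_sd <- suppressWarnings(as.numeric(vc[-nrow(vc), "StdDev"]))
        names(re_sd) <- rownames(vc)[-nrow(vc)]
        list(kind = "nlme", beta = nlme::fixef(m),
             se = sqrt(diag(m$varFix)), re_sd = re_sd, sigma_e = m$sigma,
             loglik = as.numeric(stats::logLik(m)),
             k = attr(stats::logLik(m), "df"),
             pe = nlme::ranef(m), model = m)
      } else {
        ## exact marginal ML (Gauss-Hermite) for one random ODE parameter
        g <- density_ml_fit(tr, spec, start)
        pe <- data.frame(u = unname(g$modes), row.names = names(g$modes))
        names(pe) <- spec
        list(kind = "gh", beta = g$beta, se = g$se,
             re_sd = stats::setNames(g$sd_u, spec), sigma_e = g$sigma_e,
             loglik = g$loglik, k = 5L, pe = pe, model = NULL)
      }
    }, error = function(e) e)
    ok <- !inherits(f, "error")
    rows[[spec]] <- data.frame(
      spec = spec, converged = ok,
      loglik = if (ok) f$loglik else NA_real_,
      bic = if (ok) -2 * f$loglik + f$k * log(nrow(tr)) else NA_real_,
      stringsAsFactors = FALSE)
    if (ok) fits[[spec]] <- f
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  if (!length(fits))
    stop("no density-model variant converged; last error: ",
         conditionMessage(f))
  best_spec <- tab$spec[which.min(tab$bic)]
  f <- fits[[best_spec]]
  structure(list(beta = stats::setNames(unname(f$beta), c("b0", "b1", "b2")),
                 se = stats::setNames(unname(f$se), c("b0", "b1", "b2")),
                 random_effect_spec = best_spec, re_sd = f$re_sd,
                 sigma_e = f$sigma_e, loglik = f$loglik,
                 bic = tab$bic[tab$spec == best_spec],
                 comparison = tab, plot_effects = f$pe, n_obs = nrow(tr),
                 model = f$model),
            class = "density_fit")
}

#' Fit the negative-binomial mortality model (D-P-NBME)
#'
#' Death counts per plot follow a negative binomial with log link
#' \eqn{\ln\mu = \beta_0 + u_{0i} + \beta_1 \ln dg_0 + \beta_2 \ln N_0 + \ln\Delta dg}
#' (the last term a fixed offset, so the measured dg increment enters as
#' is) and variance \eqn{\mu + \mu^2/\theta}. Per-hectare mortality is
#' converted to plot-level counts via the plot area; the area ratio enters
#' as a second offset so the coefficients stay on the per-hectare scale.
#'
#' @param transitions data.frame from [build_transitions()] (or with
#'   columns `deaths`, `n0`, `dg0`, `delta_dg`, `area_m2`).
#' @return object of class `mortality_fit`: `beta` (b0, b1, b2), `se`,
#'   `theta`, `var_u0`, `loglik`, `bic`, `plot_effects`.
#' @export
fit_mortality_nbme <- function(transitions) {
  tr <- transitions
  if (nrow(tr) < 10L) stop("need >= 10 transitions")
  if (!"deaths" %in% names(tr)) {
    if (all(is.na(tr$area_m2))) {
      warning("plot area missing; assuming 1-ha plots for count conversion")
      tr$area_m2 <- 10000
    }
    tr$deaths <- as.integer(round(tr$delta_n * tr$area_m2 / 10000))
  }
  if (all(tr$deaths == 0)) stop("no mortality signal")
  tr$l_dg0 <- ln(tr$dg0)
  tr$l_n0 <- ln(tr$n0)
  tr$off <- ln(tr$delta_dg) + ln(tr$area_m2 / 10000)
  fit <- glmmTMB::glmmTMB(deaths ~ l_dg0 + l_n0 + offset(off) + (1 | plot_id),
                          family = glmmTMB::nbinom2, data = tr)
  theta <- stats::sigma(fit)
  if (theta > 1e4) warning("theta very large; Poisson-like dispersion")
  co <- summary(fit)$coefficients$cond
  vc <- glmmTMB::VarCorr(fit)$cond$plot_id
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  re <- glmmTMB::ranef(fit)$cond$plot_id
  structure(list(beta = stats::setNames(co[, "Estimate"], c("b0", "b1", "b2")),
                 se = stats::setNames(co[, "Std. Error"], c("b0", "b1", "b2")),
                 theta = theta, var_u0 = as.numeric(vc[1, 1]),
                 loglik = ll, bic = -2 * ll + k * log(nrow(tr)),
                 plot_effects = data.frame(plot_id = rownames(re),
                                           u0 = re[["(Intercept)"]],
                                           stringsAsFactors = FALSE),
                 n_obs = nrow(tr), model = fit),
            class = "mortality_fit")
}

## Anchored mean function for the first-measurement strategy; the per-plot
## denominator (the gap between the Reineke part at the first measurement
## and the observed first ln dg) is clamped away from zero.
traj_model <- function(lnN, lnN1st, ldg1st, a0, a1, a2, a3) {
  denom <- pmax(a0 + a1 * lnN1st - ldg1st, 1e-6)
  a0 + a1 * lnN - ((a0 * a2)^2 / denom) * exp(-a3 * (lnN1st - lnN))
}

#' Fit the first-measurement trajectory model (D-P-NLME)
#'
#' Predicts ln dg from ln N with a deviation term anchored at each plot's
#' first measurement, so a stand's approach to the self-thinning line is
#' governed by its starting position. Fitted by nonlinear mixed ML with a
#' plot random intercept on alpha0 (set `random = FALSE` for plain
#' nonlinear least squares).
#'
#' @param plots plot series with `plot_id`, `occasion`, `n_ha`, `dg_cm`
#'   (plots with >= 2 occasions).
#' @param random logical: random intercept on alpha0.
#' @param start optional c(a0, a1, a2, a3).
#' @return object of class `trajectory_fit`: `alpha` (a0..a3), `se`,
#'   `re_sd`, `sigma_e`, `loglik`, `bic`.
#' @export
fit_trajectory_nlme <- function(plots, random = TRUE, start = NULL) {
  keep <- plots$plot_id %in% names(which(table(plots$plot_id) >= 2L))
  dat <- plots[keep, , drop = FALSE]
  if (!nrow(dat)) stop("no plots with >= 2 occasions")
  dat <- dat[order(dat$plot_id, dat$occasion), , drop = FALSE]
  first <- dat[!duplicated(dat$plot_id), c("plot_id", "n_ha", "dg_cm")]
  names(first) <- c("plot_id", "n1st", "dg1st")
  dat <- merge(dat, first, by = "plot_id", sort = FALSE)
  dat$lnN <- ln(dat$n_ha); dat$ldg <- ln(dat$dg_cm)
  dat$lnN1st <- ln(dat$n1st); dat$ldg1st <- ln(dat$dg1st)
  ## the first measurement is the trajectory's conditioning anchor, not a
  ## response: its deviation from the curve is the plot's frontier gap
  dat <- dat[dat$occasion != stats::ave(dat$occasion, dat$plot_id,
                                        FUN = min), , drop = FALSE]
  if (is.null(start)) {
    cf <- stats::coef(stats::lm(ldg ~ lnN, data = dat))
    start <- c(a0 = unname(cf[1]) + 0.3, a1 = unname(cf[2]), a2 = 0.3, a3 = 1)
  }
  form <- ldg ~ a0 + a1 * lnN -
    ((a0 * a2)^2 / pmax(a0 + a1 * lnN1st - ldg1st, 1e-6)) *
    exp(-a3 * (lnN1st - lnN))
  fx <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = as.list(start),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (!is.null(fx)) start <- stats::coef(fx)
  fit <- NULL; used_random <- random
  if (random) {
    fit <- tryCatch(
      nlme::nlme(form,
                 fixed = a0 + a1 + a2 + a3 ~ 1, random = a0 ~ 1,
                 groups = ~plot_id, data = dat, start = unname(start),
                 method = "ML",
                 control = nlme::nlmeControl(maxIter = 200, msMaxIter = 200,
                                             returnObject = TRUE)),
      error = function(e) NULL)
    ## convergence guard: a mixed fit that drifts far from the
    ## least-squares solution has left the basin of attraction
    if (!is.null(fit) && !is.null(fx) &&
        any(abs(nlme::fixef(fit) - stats::coef(fx)) >
              pmax(2, abs(stats::coef(fx)))))
      fit <- NULL
    if (is.null(fit)) {
      warning("mixed trajectory fit failed; falling back to nonlinear least squares")
      used_random <- FALSE
    }
  }
  if (!used_random) {
    if (is.null(fx)) stop("trajectory fit did not converge")
    fit <- fx
  }
  if (used_random) {
    alpha <- nlme::fixef(fit)
    se <- sqrt(diag(fit$varFix))
    vc <- suppressWarnings(nlme::VarCorr(fit))
    re_sd <- suppressWarnings(as.numeric(vc[1, "StdDev"]))
    sigma_e <- fit$sigma
  } else {
    alpha <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    re_sd <- 0
    sigma_e <- summary(fit)$sigma
  }
  if (alpha[2] >= 0) warning("alpha1 >= 0: size does not decline with density")
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  structure(list(alpha = stats::setNames(unname(alpha), paste0("a", 0:3)),
                 se = stats::setNames(unname(se), paste0("a", 0:3)),
                 re_sd = re_sd, sigma_e = sigma_e, loglik = ll,
                 bic = -2 * ll + k * log(nrow(dat)),
                 random = used_random, n_obs = nrow(dat), model = fit),
            class = "trajectory_fit")
}

#' @export
print.density_fit <- function(x, ...) {
  cat("Closed-form density model fit (ML):\n")
  cat(sprintf("  beta = (%.4f, %.4f, %.4f), random on {%s}, sigma_e = %.4g\n",
              x$beta[1], x$beta[2], x$beta[3], x$random_effect_spec, x$sigma_e))
  cat(sprintf("  logLik = %.2f  BIC = %.1f\n", x$loglik, x$bic))
  invisible(x)
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat("Negative-binomial mortality fit:\n")
  cat(sprintf("  beta = (%.4f, %.4f, %.4f)  theta = %.3g  var(u0) = %.4g\n",
              x$beta[1], x$beta[2], x$beta[3], x$theta, x$var_u0))
  invisible(x)
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("First-measurement trajectory fit:\n")
  cat(sprintf("  alpha = (%.4f, %.4f, %.4f, %.4f)  sigma_e = %.4g\n",
              x$alpha[1], x$alpha[2], x$alpha[3], x$alpha[4], x$sigma_e))
  invisible(x)
}
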