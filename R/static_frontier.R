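## Static site-level frontier strategies: random-coefficient Reineke model,
## linear quantile mixed model (asymmetric Laplace marginal likelihood with
## Gauss-Hermite quadrature) and random-effects stochastic frontier.

check_loss <- function(z, tau) z * (tau - (z < 0))

## log asymmetric-Laplace density with check-loss kernel
ald_logdens <- function(r, sigma, tau) {
  log(tau * (1 - tau)) - log(sigma) - check_loss(r / sigma, tau)
}

plots_xy <- function(plots) {
  stopifnot(all(c("plot_id", "n_ha", "dg_cm") %in% names(plots)))
  if (any(plots$n_ha <= 0) || any(plots$dg_cm <= 0))
    stop("n_ha and dg_cm must be positive")
  list(y = ln(plots$n_ha), x = ln(plots$dg_cm),
       g = factor(plots$plot_id))
}

#' Fit the random-coefficient Reineke model (S-P-LME)
#'
#' Maximum-likelihood fit of
#' \eqn{\ln N_{ij} = (\beta_0+u_{0i}) + (\beta_1+u_{1i})\ln dg_{ij} + e_{ij}}
#' with plot random effects on both coefficients. If the random-slope model
#' is singular or fails, the model is refit with a random intercept only
#' (with a warning).
#'
#' @param plots data.frame with `plot_id`, `n_ha`, `dg_cm`.
#' @param random `"both"` (intercept and slope) or `"intercept"`.
#' @param method `"ML"` (default, so BIC is comparable across strategies)
#'   or `"REML"`.
#' @return object of class `lme_fit`: coefficients, SEs, variance
#'   components, log-likelihood, BIC and predicted plot effects.
#' @export
fit_lme_reineke <- function(plots, random = c("both", "intercept"),
                            method = c("ML", "REML")) {
  random <- match.arg(random)
  method <- match.arg(method)
  d <- plots_xy(plots)
  if (length(unique(d$x)) < 2L) stop("need >= 2 distinct dg values")
  if (nlevels(d$g) < 2L) stop("need >= 2 plots")
  df <- data.frame(y = d$y, x = d$x, g = d$g)
  fit <- NULL
  if (random == "both") {
    fit <- tryCatch(
      nlme::lme(y ~ x, random = ~ x | g, data = df, method = method,
                control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                           msMaxIter = 200, returnObject = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      vc <- suppressWarnings(nlme::VarCorr(fit))
      if (any(!is.finite(suppressWarnings(as.numeric(vc[, "StdDev"]))))) fit <- NULL
    }
    if (is.null(fit)) {
      warning("random-slope fit singular or failed; refitting with random intercept only")
      random <- "intercept"
    }
  }
  if (random == "intercept") {
    fit <- nlme::lme(y ~ x, random = ~ 1 | g, data = df, method = method,
                     control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                                msMaxIter = 200, returnObject = TRUE))
  }
  beta <- nlme::fixef(fit)
  se <- sqrt(diag(fit$varFix))
  vc <- suppressWarnings(nlme::VarCorr(fit))
  re <- nlme::ranef(fit)
  if (random == "both") {
    var_u0 <- as.numeric(vc["(Intercept)", "Variance"])
    var_u1 <- as.numeric(vc["x", "Variance"])
    corr_u <- suppressWarnings(as.numeric(vc["x", "Corr"]))
    pe <- data.frame(plot_id = rownames(re), u0 = re[["(Intercept)"]],
                     u1 = re[["x"]], stringsAsFactors = FALSE)
  } else {
    var_u0 <- as.numeric(vc["(Intercept)", "Variance"])
    var_u1 <- 0
    corr_u <- NA_real_
    pe <- data.frame(plot_id = rownames(re), u0 = re[["(Intercept)"]],
                     u1 = 0, stringsAsFactors = FALSE)
  }
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  structure(list(beta0 = unname(beta[1]), beta1 = unname(beta[2]),
                 se_beta0 = se[1], se_beta1 = se[2],
                 var_u0 = var_u0, var_u1 = var_u1, corr_u = corr_u,
                 var_e = fit$sigma^2, loglik = ll,
                 bic = -2 * ll + k * log(nrow(df)),
                 plot_effects = pe, n_obs = nrow(df), random = random,
                 model = fit),
            class = "lme_fit")
}

## ---------------------------------------------------------------------------
## Asymmetric-Laplace mixed machinery (shared with the tree-level strategy)

## Per-plot marginal log-likelihood contributions: Gaussian random
## intercept integrated by Gauss-Hermite quadrature.
## theta = (beta, log sigma, log sd_u0).
ald_mixed_lli <- function(theta, y, X, gi, tau, gh) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1L])
  s0 <- exp(theta[p + 2L])
  r <- y - drop(X %*% beta)
  shift <- sqrt(2) * s0 * gh$x
  R <- outer(r, shift, "-")
  L <- ald_logdens(R, sigma, tau)
  Gm <- rowsum(L, gi)                      # groups x nodes
  logsumexp(sweep(Gm, 2L, log(gh$w), "+"))
}

ald_mixed_nll <- function(theta, y, X, gi, tau, gh)
  -sum(ald_mixed_lli(theta, y, X, gi, tau, gh))

## Pinball (check-loss) minimization: iteratively reweighted least squares,
## a Nelder-Mead polish, then a local vertex refinement (an exact solution
## interpolates p observations, so the best basis among the
## smallest-residual points is examined directly). Used for starting
## values and for the zero-random-variance path.
pinball_fit <- function(y, X, tau, maxit = 200L, delta = 1e-8) {
  p <- ncol(X)
  beta <- stats::coef(stats::lm.fit(X, y))
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    w <- abs(tau - (r < 0)) / pmax(abs(r), delta)
    bnew <- stats::coef(stats::lm.wfit(X, y, w))
    if (max(abs(bnew - beta)) < 1e-12) { beta <- bnew; break }
    beta <- bnew
  }
  obj <- function(b) sum(check_loss(y - drop(X %*% b), tau))
  o <- stats::optim(beta, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  beta <- o$par; best <- o$value
  ## vertex refinement over the K nearest observations
  r <- y - drop(X %*% beta)
  K <- min(length(y), max(12L, 3L * p))
  cand <- order(abs(r))[seq_len(K)]
  for (s in utils::combn(cand, p, simplify = FALSE)) {
    Xs <- X[s, , drop = FALSE]
    if (abs(det(Xs)) < 1e-10) next
    b <- tryCatch(solve(Xs, y[s]), error = function(e) NULL)
    if (is.null(b)) next
    v <- obj(b)
    if (v < best) { best <- v; beta <- b }
  }
  beta
}

## Posterior modes of the plot random intercepts.
ald_mixed_modes <- function(y, X, gi, beta, sigma, s0, tau) {
  r <- y - drop(X %*% beta)
  lev <- levels(gi)
  vapply(lev, function(l) {
    ri <- r[gi == l]
    if (s0 < 1e-8) return(0)
    f <- function(u) -sum(ald_logdens(ri - u, sigma, tau)) + u^2 / (2 * s0^2)
    stats::optimize(f, c(-5 * s0 - 1, 5 * s0 + 1))$minimum
  }, numeric(1))
}

## Core ALD mixed fitter on a general design matrix (no intercept added).
ald_mixed_fit <- function(y, X, group, tau, nodes = 15L, fix_var_u0 = NULL,
                          restarts = 5L, seed_jitter = 7L) {
  gi <- factor(group)
  p <- ncol(X)
  gh <- gh_rule(nodes)
  beta0 <- pinball_fit(y, X, tau)
  r0 <- y - drop(X %*% beta0)
  sig0 <- max(mean(check_loss(r0, tau)), 1e-6)

  if (!is.null(fix_var_u0) && fix_var_u0 == 0) {
    ## zero-variance path: profile sigma, minimize the pinball loss
    beta <- beta0
    sigma <- mean(check_loss(y - drop(X %*% beta), tau))
    ll <- sum(ald_logdens(y - drop(X %*% beta), sigma, tau))
    V <- opg_covariance(function(th) {
      rowsum(ald_logdens(y - drop(X %*% th[seq_len(p)]), exp(th[p + 1L]), tau),
             gi)[, 1L]
    }, c(beta, log(sigma)))
    se <- suppressWarnings(sqrt(diag(V)))[seq_len(p)]
    return(list(beta = beta, se_beta = se, sigma = sigma, sd_u0 = 0,
                loglik = ll, nodes = nodes, tau = tau,
                modes = stats::setNames(rep(0, nlevels(gi)), levels(gi))))
  }

  nll <- function(th) ald_mixed_nll(th, y, X, gi, tau, gh)
  start <- c(beta0, log(sig0), log(max(sig0, 0.05)))
  best <- stats::optim(start, nll, method = "BFGS",
                       control = list(maxit = 400, reltol = 1e-10))
  best <- with_local_seed(seed_jitter, {
    b <- best
    for (r in seq_len(restarts - 1L)) {
      st <- start + stats::rnorm(length(start), 0, 0.15)
      o <- tryCatch(stats::optim(st, nll, method = "BFGS",
                                 control = list(maxit = 400, reltol = 1e-10)),
                    error = function(e) NULL)
      if (!is.null(o) && o$value < b$value) b <- o
    }
    b
  })
  best <- stats::optim(best$par, nll, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 3000))
  th <- best$par
  V <- opg_covariance(function(t) ald_mixed_lli(t, y, X, gi, tau, gh), th)
  se_all <- suppressWarnings(sqrt(diag(V)))
  beta <- th[seq_len(p)]
  sigma <- exp(th[p + 1L]); s0 <- exp(th[p + 2L])
  list(beta = beta, se_beta = se_all[seq_len(p)], sigma = sigma, sd_u0 = s0,
       loglik = -best$value, nodes = nodes, tau = tau,
       modes = ald_mixed_modes(y, X, gi, beta, sigma, s0, tau))
}

#' Fit the linear quantile mixed model (S-P-LQMM)
#'
#' Fits the conditional tau-quantile of ln N on ln dg with a Gaussian plot
#' random intercept, by maximizing the marginal likelihood built from the
#' asymmetric Laplace density (whose kernel is the quantile check loss),
#' integrating the random effect with Gauss-Hermite quadrature. Standard
#' errors come from the numerical Hessian, or from a plot-resampling
#' bootstrap.
#'
#' @param plots data.frame with `plot_id`, `n_ha`, `dg_cm`.
#' @param tau quantile in (0, 1); 0.95 targets the self-thinning frontier.
#' @param nodes Gauss-Hermite nodes.
#' @param var_u0 set to 0 to force the random-intercept variance to zero
#'   (pure quantile regression); `NULL` estimates it.
#' @param se `"hessian"` (default, outer-product-of-gradients from the
#'   per-plot scores) or `"bootstrap"`.
#' @param boot_reps bootstrap replicates when `se = "bootstrap"`.
#' @param boot_seed seed for the bootstrap resampling.
#' @param restarts jittered optimizer restarts.
#' @return object of class `lqmm_fit`.
#' @export
fit_lqmm <- function(plots, tau = 0.95, nodes = 15L, var_u0 = NULL,
                     se = c("hessian", "bootstrap"), boot_reps = 100L,
                     boot_seed = 1L, restarts = 5L) {
  se <- match.arg(se)
  stopifnot(tau > 0, tau < 1)
  d <- plots_xy(plots)
  X <- cbind(`(Intercept)` = 1, x = d$x)
  f <- ald_mixed_fit(d$y, X, d$g, tau, nodes = nodes, fix_var_u0 = var_u0,
                     restarts = restarts)
  se_beta <- f$se_beta
  if (se == "bootstrap") {
    set.seed(boot_seed)
    lev <- levels(d$g)
    bs <- matrix(NA_real_, boot_reps, 2L)
    for (b in seq_len(boot_reps)) {
      take <- sample(lev, length(lev), replace = TRUE)
      idx <- unlist(lapply(seq_along(take), function(k) which(d$g == take[k])))
      gi <- rep(seq_along(take), times = vapply(take, function(l) sum(d$g == l), 1L))
      fb <- tryCatch(ald_mixed_fit(d$y[idx], X[idx, , drop = FALSE], gi, tau,
                                   nodes = nodes, fix_var_u0 = var_u0,
                                   restarts = 1L),
                     error = function(e) NULL)
      if (!is.null(fb)) bs[b, ] <- fb$beta
    }
    se_beta <- apply(bs, 2L, stats::sd, na.rm = TRUE)
  }
  n <- length(d$y); k <- length(f$beta) + 2L
  structure(list(tau = tau, beta0_tau = unname(f$beta[1]),
                 beta1_tau = unname(f$beta[2]),
                 se_beta0 = se_beta[1], se_beta1 = se_beta[2],
                 var_u0 = f$sd_u0^2, sigma_ala = f$sigma,
                 loglik = f$loglik, bic = -2 * f$loglik + k * log(n),
                 plot_effects = data.frame(plot_id = names(f$modes),
                                           u0 = unname(f$modes),
                                           stringsAsFactors = FALSE),
                 nodes = f$nodes, n_obs = n),
            class = "lqmm_fit")
}

#' Select the frontier quantile
#'
#' Fits the quantile mixed model at each candidate tau and returns the one
#' minimizing the summed estimated sampling variances of the intercept and
#' slope, together with the full comparison table.
#'
#' @param plots data.frame with `plot_id`, `n_ha`, `dg_cm`.
#' @param taus candidate quantiles in (0, 1).
#' @param ... passed to [fit_lqmm()].
#' @return list with `tau` (selected), `table` (tau, coefficients, SEs,
#'   summed variance) and `fits`.
#' @export
select_quantile <- function(plots, taus = c(0.90, 0.95, 0.99), ...) {
  stopifnot(all(taus > 0 & taus < 1))
  fits <- list(); rows <- list()
  for (tau in taus) {
    f <- tryCatch(fit_lqmm(plots, tau = tau, ...), error = function(e) {
      warning(sprintf("tau = %.3g failed: %s", tau, conditionMessage(e)))
      NULL
    })
    if (is.null(f)) next
    fits[[as.character(tau)]] <- f
    rows[[as.character(tau)]] <- data.frame(
      tau = tau, beta0 = f$beta0_tau, beta1 = f$beta1_tau,
      se_beta0 = f$se_beta0, se_beta1 = f$se_beta1,
      var_sum = f$se_beta0^2 + f$se_beta1^2)
  }
  if (!length(rows)) stop("all candidate quantiles failed")
  tab <- do.call(rbind, rows)
  best <- tab$tau[which.min(tab$var_sum)]
  list(tau = best, table = tab, fits = fits)
}

## ---------------------------------------------------------------------------
## Stochastic frontier with plot random effects

## log of the composed-error density: eps = V - U, V ~ N(0, sv^2),
## U ~ |N(0, su^2)|: f(eps) = (2/s) phi(eps/s) Phi(-eps * lambda / s).
sfr_logdens <- function(eps, sv, su) {
  s <- sqrt(sv^2 + su^2)
  lam <- su / sv
  log(2) - log(s) + stats::dnorm(eps / s, log = TRUE) +
    stats::pnorm(-eps * lam / s, log.p = TRUE)
}

sfr_lli <- function(theta, y, X, gi, gh, draws = NULL) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sv <- exp(theta[p + 1L]); su <- exp(theta[p + 2L]); sw <- exp(theta[p + 3L])
  r <- y - drop(X %*% beta)
  if (is.null(draws)) {
    shift <- sqrt(2) * sw * gh$x
    lw <- log(gh$w)
  } else {
    shift <- sw * draws
    lw <- rep(-log(length(draws)), length(draws))
  }
  R <- outer(r, shift, "-")
  L <- sfr_logdens(R, sv, su)
  Gm <- rowsum(L, gi)
  logsumexp(sweep(Gm, 2L, lw, "+"))
}

sfr_nll <- function(theta, y, X, gi, gh, draws = NULL)
  -sum(sfr_lli(theta, y, X, gi, gh, draws))

#' Fit the random-effects stochastic frontier model (S-P-SFMM)
#'
#' Maximum likelihood for \eqn{\ln N = X\beta + w_i + V - U} with Gaussian
#' noise V, half-normal inefficiency U (so the frontier \eqn{X\beta + w_i}
#' bounds the data from above up to V) and a Gaussian plot random
#' intercept, integrated by Gauss-Hermite quadrature or simulated ML.
#'
#' @param plots data.frame with `plot_id`, `n_ha`, `dg_cm`.
#' @param nodes Gauss-Hermite nodes (quadrature method).
#' @param method `"quadrature"` (default) or `"sml"` (simulated ML with
#'   fixed standard-normal draws).
#' @param sml_draws number of draws for simulated ML.
#' @param restarts jittered optimizer restarts.
#' @return object of class `sfmm_fit` with frontier coefficients, sigma_v,
#'   sigma_u, lambda, random-intercept variance, log-likelihood, BIC and
#'   plot effects.
#' @export
fit_sfmm <- function(plots, nodes = 15L, method = c("quadrature", "sml"),
                     sml_draws = 200L, restarts = 5L) {
  method <- match.arg(method)
  d <- plots_xy(plots)
  X <- cbind(`(Intercept)` = 1, x = d$x)
  gi <- d$g
  gh <- gh_rule(nodes)
  draws <- NULL
  if (method == "sml") {
    draws <- with_local_seed(202L, stats::rnorm(sml_draws))
    draws <- c(draws, -draws)  # antithetic
  }
  ols <- stats::lm.fit(X, d$y)
  s_r <- stats::sd(ols$residuals)
  start <- c(ols$coefficients + c(s_r, 0), log(s_r * 0.6), log(s_r * 0.8),
             log(max(s_r * 0.5, 0.02)))
  nll <- function(th) sfr_nll(th, d$y, X, gi, gh, draws)
  best <- stats::optim(start, nll, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-10))
  best <- with_local_seed(11L, {
    b <- best
    for (r in seq_len(restarts - 1L)) {
      st <- start + stats::rnorm(length(start), 0, 0.2)
      o <- tryCatch(stats::optim(st, nll, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-10)),
                    error = function(e) NULL)
      if (!is.null(o) && o$value < b$value) b <- o
    }
    b
  })
  best <- stats::optim(best$par, nll, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 4000))
  th <- best$par
  p <- ncol(X)
  beta <- th[seq_len(p)]
  sv <- exp(th[p + 1L]); su <- exp(th[p + 2L]); sw <- exp(th[p + 3L])
  if (su / sv < 1e-3)
    warning("no inefficiency signal; frontier ~ OLS")
  V <- opg_covariance(function(t) sfr_lli(t, d$y, X, gi, gh, draws), th)
  se_all <- suppressWarnings(sqrt(diag(V)))
  ## posterior modes of w
  r <- d$y - drop(X %*% beta)
  modes <- vapply(levels(gi), function(l) {
    ri <- r[gi == l]
    if (sw < 1e-8) return(0)
    f <- function(w) -sum(sfr_logdens(ri - w, sv, su)) + w^2 / (2 * sw^2)
    stats::optimize(f, c(-5 * sw - 1, 5 * sw + 1))$minimum
  }, numeric(1))
  n <- length(d$y); k <- p + 3L
  ll <- -best$value
  structure(list(beta0 = unname(beta[1]), beta1 = unname(beta[2]),
                 se_beta0 = se_all[1], se_beta1 = se_all[2],
                 sigma_v = sv, sigma_u = su, lambda = su / sv,
                 var_u0re = sw^2, loglik = ll, bic = -2 * ll + k * log(n),
                 plot_effects = data.frame(plot_id = names(modes),
                                           u0 = unname(modes),
                                           stringsAsFactors = FALSE),
                 method = method, n_obs = n),
            class = "sfmm_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat("Random-coefficient Reineke fit (ML):\n")
  cat(sprintf("  ln N = %.4f %+.4f ln dg   (SE %.4f, %.4f)\n",
              x$beta0, x$beta1, x$se_beta0, x$se_beta1))
  cat(sprintf("  var(u0) = %.4g  var(u1) = %.4g  var(e) = %.4g  BIC = %.1f\n",
              x$var_u0, x$var_u1, x$var_e, x$bic))
  invisible(x)
}

#' @export
print.lqmm_fit <- function(x, ...) {
  cat(sprintf("Linear quantile mixed fit (tau = %.2f):\n", x$tau))
  cat(sprintf("  ln N = %.4f %+.4f ln dg   (SE %.4f, %.4f)\n",
              x$beta0_tau, x$beta1_tau, x$se_beta0, x$se_beta1))
  cat(sprintf("  var(u0) = %.4g  sigma_ALD = %.4g  logLik = %.2f\n",
              x$var_u0, x$sigma_ala, x$loglik))
  invisible(x)
}

#' @export
print.sfmm_fit <- function(x, ...) {
  cat("Stochastic frontier mixed fit (half-normal inefficiency):\n")
  cat(sprintf("  frontier: ln N = %.4f %+.4f ln dg\n", x$beta0, x$beta1))
  cat(sprintf("  sigma_v = %.4g  sigma_u = %.4g  lambda = %.3g  var(w) = %.4g\n",
              x$sigma_v, x$sigma_u, x$lambda, x$var_u0re))
  invisible(x)
}
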