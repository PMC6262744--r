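## Self-thinning lines from every fitted strategy, plot-level maximum
## stand density index, Scheffe comparison across strategies, and the
## carrying-capacity regression on covariates.

new_thinning_line <- function(strategy, intercept, slope, provenance,
                              intercept_unshifted = NA_real_) {
  if (is.finite(slope) && slope >= 0)
    warning("self-thinning slope is non-negative; check the fit")
  structure(list(strategy = strategy, intercept = intercept, slope = slope,
                 provenance = provenance,
                 intercept_unshifted = intercept_unshifted),
            class = "thinning_line")
}

#' @export
print.thinning_line <- function(x, ...) {
  cat(sprintf("Self-thinning line [%s, %s]: ln N = %.4f %+.4f ln dg\n",
              x$strategy, x$provenance, x$intercept, x$slope))
  invisible(x)
}

#' Self-thinning line from the upper confidence bound of the intercept
#'
#' Shifts a mean-model (or quantile-model) intercept to the upper level of
#' its confidence interval, \eqn{b_0 = \hat\beta_0 + z \cdot SE(\hat\beta_0)}
#' with z = 1.96 by default (set `exact_t = TRUE` for the t quantile); the
#' slope passes through unchanged.
#'
#' @param fit an `lme_fit` or `lqmm_fit`.
#' @param alpha two-sided level (default 0.05).
#' @param exact_t use the t quantile with the fit's residual df instead of
#'   the conventional 1.96 multiplier.
#' @return a `thinning_line`.
#' @export
line_from_upper_ci <- function(fit, alpha = 0.05, exact_t = FALSE) {
  if (inherits(fit, "lme_fit")) {
    b0 <- fit$beta0; b1 <- fit$beta1; se <- fit$se_beta0; strat <- "S-P-LME"
  } else if (inherits(fit, "lqmm_fit")) {
    b0 <- fit$beta0_tau; b1 <- fit$beta1_tau; se <- fit$se_beta0
    strat <- "S-P-LQMM"
  } else stop("fit must be an lme_fit or lqmm_fit")
  if (!is.finite(se))
    stop("intercept SE unavailable; refit with the bootstrap SE option")
  z <- if (isTRUE(exact_t)) stats::qt(1 - alpha / 2, df = max(fit$n_obs - 2L, 1L))
       else if (alpha == 0.05) 1.96 else stats::qnorm(1 - alpha / 2)
  new_thinning_line(strat, b0 + z * se, b1, "upper-CI", intercept_unshifted = b0)
}

#' Self-thinning line from a stochastic frontier fit
#'
#' The estimated frontier is the boundary itself (the one-sided
#' inefficiency term already places the data below it), so intercept and
#' slope pass through unshifted.
#'
#' @param fit an `sfmm_fit`.
#' @return a `thinning_line`.
#' @export
line_from_frontier <- function(fit) {
  stopifnot(inherits(fit, "sfmm_fit"))
  new_thinning_line("S-P-SFMM", fit$beta0, fit$beta1, "frontier",
                    intercept_unshifted = fit$beta0)
}

#' Self-thinning line from the mortality ODE parameters
#'
#' The attractor of \eqn{dN/d\,dg = -e^{\beta_0} dg^{\beta_1} N^{\beta_2}} is
#' the log-linear line with
#' \deqn{slope = \frac{1+\beta_1}{1-\beta_2}, \qquad
#'   intercept = \frac{\beta_0 + \ln(\beta_2-1) - \ln(\beta_1+1)}{1-\beta_2}.}
#'
#' @param beta0,beta1,beta2 ODE parameters (beta2 > 1, beta1 > -1); or pass
#'   a `density_fit`/`mortality_fit` as `beta0` with the others missing.
#' @param strategy label recorded on the line.
#' @return a `thinning_line`.
#' @examples
#' line_from_ode_params(0, 1, 2)   # intercept ln 2, slope -2
#' @export
line_from_ode_params <- function(beta0, beta1, beta2, strategy = "D-P-LME") {
  if (inherits(beta0, "density_fit")) {
    b <- beta0$beta; strategy <- "D-P-LME"
    beta0 <- b[1]; beta1 <- b[2]; beta2 <- b[3]
  } else if (inherits(beta0, "mortality_fit")) {
    b <- beta0$beta; strategy <- "D-P-NBME"
    beta0 <- b[1]; beta1 <- b[2]; beta2 <- b[3]
  }
  if (beta2 <= 1) stop("beta2 must exceed 1 for a finite attractor")
  if (beta1 <= -1) stop("beta1 must exceed -1 for a finite attractor")
  sl <- (1 + beta1) / (1 - beta2)
  ic <- (beta0 + ln(beta2 - 1) - ln(beta1 + 1)) / (1 - beta2)
  new_thinning_line(strategy, unname(ic), unname(sl), "attractor",
                    intercept_unshifted = unname(ic))
}

#' Self-thinning line from the trajectory fit
#'
#' Inverts the Reineke part of the trajectory model
#' (\eqn{\ln dg = \alpha_0 + \alpha_1 \ln N}) to the density scale:
#' slope \eqn{1/\alpha_1}, intercept \eqn{-\alpha_0/\alpha_1}.
#'
#' @param fit a `trajectory_fit`, or numeric c(alpha0, alpha1).
#' @return a `thinning_line`.
#' @export
line_from_trajectory <- function(fit) {
  a <- if (inherits(fit, "trajectory_fit")) fit$alpha else fit
  if (a[2] == 0) stop("alpha1 = 0: line undefined")
  new_thinning_line("D-P-NLME", unname(-a[1] / a[2]), unname(1 / a[2]),
                    "reversed-Reineke",
                    intercept_unshifted = unname(-a[1] / a[2]))
}

#' Maximum density at a reference diameter
#'
#' \eqn{N_{max} = \exp(b_0 + u_i + b_1 \ln d_{base})}: the maximum stand
#' density index at the base diameter. Supplying per-plot random intercepts
#' yields plot-level capacity estimates.
#'
#' @param line a `thinning_line`.
#' @param dbase reference diameter, cm (default 25.4).
#' @param plot_effect scalar or vector of plot intercept offsets.
#' @return stems/ha (vectorized over `plot_effect`).
#' @examples
#' l <- line_from_ode_params(0, 1, 2)
#' predict_nmax(l, dbase = 1)   # exp(ln 2) = 2
#' @export
predict_nmax <- function(line, dbase = 25.4, plot_effect = 0) {
  stopifnot(inherits(line, "thinning_line"), dbase > 0)
  exp(line$intercept + plot_effect + line$slope * ln(dbase))
}

#' Plot-level capacity estimates for a set of fitted strategies
#'
#' Applies each strategy's self-thinning line at the base diameter, using
#' predicted plot random effects where the strategy has them (tree-level
#' capacity uses each plot's mean specific gravity instead of a line).
#'
#' @param fits named list of fitted strategies; recognized names are
#'   `"S-P-LME"`, `"S-P-LQMM"`, `"S-P-SFMM"`, `"S-T-LME"`, `"D-P-LME"`,
#'   `"D-P-NBME"`, `"D-P-NLME"`.
#' @param dbase reference diameter (cm).
#' @param ducey_covariates covariate table (for the `"S-T-LME"` entry).
#' @return data.frame `plot_id`, `strategy`, `sdi_max`, `dbase`.
#' @export
capacity_estimates <- function(fits, dbase = 25.4, ducey_covariates = NULL) {
  out <- list()
  add <- function(pid, strat, val)
    out[[length(out) + 1L]] <<- data.frame(plot_id = pid, strategy = strat,
                                           sdi_max = val, dbase = dbase,
                                           stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (nm == "S-T-LME") {
      if (is.null(ducey_covariates))
        stop("S-T-LME capacities need the ducey covariate table")
      cv <- ducey_covariates[!duplicated(ducey_covariates$plot_id), ]
      add(cv$plot_id, nm, nmax_from_tree_fit(f, cv$sg_bar))
      next
    }
    line <- switch(nm,
                   "S-P-LME" = line_from_upper_ci(f),
                   "S-P-LQMM" = line_from_upper_ci(f),
                   "S-P-SFMM" = line_from_frontier(f),
                   "D-P-LME" = line_from_ode_params(f),
                   "D-P-NBME" = line_from_ode_params(f),
                   "D-P-NLME" = line_from_trajectory(f),
                   stop("unknown strategy: ", nm))
    pe <- f$plot_effects
    if (nm == "D-P-LME") {
      ## a plot effect on b0 shifts the attractor intercept by u/(1 - b2)
      if (!is.null(pe) && "b0" %in% names(pe)) {
        u <- pe$b0 / (1 - f$beta[3])
        add(rownames(pe), nm, predict_nmax(line, dbase, u))
      } else add("population", nm, predict_nmax(line, dbase))
    } else if (nm == "D-P-NBME") {
      u <- pe$u0 / (1 - f$beta[3])
      add(pe$plot_id, nm, predict_nmax(line, dbase, u))
    } else if (nm == "D-P-NLME") {
      ## random intercept on alpha0 maps to -u/alpha1 on the line intercept
      if (!is.null(f$model) && f$random) {
        re <- nlme::ranef(f$model)
        u <- -re[["a0"]] / f$alpha[2]
        add(rownames(re), nm, predict_nmax(line, dbase, u))
      } else add("population", nm, predict_nmax(line, dbase))
    } else {
      add(pe$plot_id, nm, predict_nmax(line, dbase, pe$u0))
    }
  }
  do.call(rbind, out)
}

## ---------------------------------------------------------------------------
## Scheffe comparison with compact letter display

#' Scheffe multiple comparison of strategy capacities
#'
#' One-way layout of plot-level SDI_max by strategy. Every pairwise
#' contrast is tested against the Scheffe critical value
#' \eqn{\sqrt{(k-1) F_{\alpha; k-1, N-k}} \cdot SE(contrast)} (simultaneous
#' over all contrasts), and the significant pairs are summarized by a
#' compact letter display (insert-and-absorb).
#'
#' @param estimates data.frame with `strategy` and `sdi_max` (e.g. from
#'   [capacity_estimates()]).
#' @param alpha familywise level.
#' @return list of class `scheffe_cmp`: `groups` (strategy, n, mean,
#'   letters), `contrasts` (pairwise table), `alpha`.
#' @export
scheffe_compare <- function(estimates, alpha = 0.05) {
  g <- factor(estimates$strategy)
  y <- estimates$sdi_max
  k <- nlevels(g)
  if (k < 2L) stop("need >= 2 strategies")
  n_i <- tabulate(g)
  if (any(n_i < 2L)) stop("each strategy needs >= 2 estimates")
  N <- length(y)
  means <- tapply(y, g, mean)
  ss_within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df2 <- N - k
  s2 <- ss_within / df2
  if (s2 <= 0) stop("zero within-group variance")
  crit <- sqrt((k - 1) * stats::qf(1 - alpha, k - 1, df2))
  pairs <- utils::combn(k, 2L)
  ct <- data.frame(
    a = levels(g)[pairs[1, ]], b = levels(g)[pairs[2, ]],
    diff = means[pairs[1, ]] - means[pairs[2, ]],
    se = sqrt(s2 * (1 / n_i[pairs[1, ]] + 1 / n_i[pairs[2, ]])))
  ct$t <- ct$diff / ct$se
  ct$significant <- abs(ct$t) > crit
  ## Scheffe p-value: P(F >= t^2/(k-1))
  ct$p <- stats::pf(ct$t^2 / (k - 1), k - 1, df2, lower.tail = FALSE)
  rownames(ct) <- NULL
  letters_tab <- cld_insert_absorb(levels(g)[order(-means)],
                                   ct[ct$significant, c("a", "b"), drop = FALSE])
  groups <- data.frame(strategy = levels(g), n = n_i,
                       mean = as.numeric(means),
                       letters = letters_tab[levels(g)],
                       stringsAsFactors = FALSE)
  groups <- groups[order(-groups$mean), ]
  rownames(groups) <- NULL
  structure(list(groups = groups, contrasts = ct, alpha = alpha,
                 critical = crit, s2 = s2, df2 = df2),
            class = "scheffe_cmp")
}

## Compact letter display by insert-and-absorb: start from one class with
## every level; for each significant pair split the classes containing
## both; absorb classes contained in others; assign letters in the given
## level order (typically by descending mean).
cld_insert_absorb <- function(lev, sig_pairs) {
  classes <- list(lev)
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs$a[r]; b <- sig_pairs$b[r]
      newc <- list()
      for (cl in classes) {
        if (a %in% cl && b %in% cl) {
          newc <- c(newc, list(setdiff(cl, a)), list(setdiff(cl, b)))
        } else newc <- c(newc, list(cl))
      }
      ## absorb duplicates / subsets
      keep <- rep(TRUE, length(newc))
      for (i in seq_along(newc)) for (j in seq_along(newc)) {
        if (i != j && keep[i] && keep[j] &&
            all(newc[[i]] %in% newc[[j]]) &&
            (length(newc[[i]]) < length(newc[[j]]) || i > j))
          keep[i] <- FALSE
      }
      classes <- newc[keep]
    }
  }
  ## order classes by first appearance of their members in lev
  first_idx <- vapply(classes, function(cl) min(match(cl, lev)), numeric(1))
  classes <- classes[order(first_idx)]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (ci in seq_along(classes))
    for (m in classes[[ci]])
      out[m] <- paste0(out[m], letters[ci])
  out
}

#' @export
print.scheffe_cmp <- function(x, ...) {
  cat(sprintf("Scheffe comparison (alpha = %.2f, critical |t| = %.3f):\n",
              x$alpha, x$critical))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

## ---------------------------------------------------------------------------
## Carrying-capacity modelling

#' Screen bioclimatic predictors of carrying capacity
#'
#' Fits the capacity regression with each candidate variable singly and
#' ranks the candidates by BIC.
#'
#' @param capacity data.frame with `plot_id` and `sdi_max`.
#' @param covariates data.frame with `plot_id` and candidate columns.
#' @param candidates column names to screen (default `bio1` ... `bio19`).
#' @return data.frame `variable`, `coef`, `se`, `r2`, `bic`, ranked by BIC.
#' @export
screen_bioclim <- function(capacity, covariates,
                           candidates = paste0("bio", 1:19)) {
  d <- merge(capacity, covariates, by = "plot_id")
  if (nrow(d) < 20L) stop("need >= 20 plots")
  rows <- list()
  for (v in candidates) {
    if (!v %in% names(d)) next
    if (stats::sd(d[[v]]) < 1e-12) {
      warning("constant covariate skipped: ", v)
      next
    }
    m <- stats::lm(stats::reformulate(v, "sdi_max"), data = d)
    s <- summary(m)
    rows[[v]] <- data.frame(variable = v,
                            coef = s$coefficients[2, 1],
                            se = s$coefficients[2, 2],
                            r2 = s$r.squared,
                            bic = stats::BIC(m),
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no usable candidates")
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$bic), ]
  rownames(tab) <- NULL
  tab
}

#' Fit the carrying-capacity model
#'
#' Least-squares regression of plot-level SDI_max on site covariates,
#' by default Shannon diversity, precipitation of the driest month (bio14),
#' and a quadratic in the primary-species basal-area share (PBA). When the
#' quadratic PBA term is negative, the implied optimum PBA
#' \eqn{-\theta_{PBA}/(2\theta_{PBA^2})} is reported.
#'
#' @param capacity data.frame with `plot_id` and `sdi_max`.
#' @param covariates data.frame with `plot_id` and the predictor columns.
#' @param formula model formula on `sdi_max` (default
#'   `sdi_max ~ shannon + bio14 + pba_pct + I(pba_pct^2)`).
#' @param standardize center and scale the (non-response) model matrix
#'   columns before fitting.
#' @return object of class `capacity_model`: `coefficients`, `se`, `sigma_e`,
#'   `rmse`, `rel_rmse` (percent of the mean response), `bic`, `pba_optimum`
#'   (NA when no concave quadratic), and the `lm` fit.
#' @export
fit_capacity_model <- function(capacity, covariates,
                               formula = sdi_max ~ shannon + bio14 +
                                 pba_pct + I(pba_pct^2),
                               standardize = FALSE) {
  d <- merge(capacity, covariates, by = "plot_id")
  if (nrow(d) < 20L) stop("need >= 20 plots")
  if (standardize) {
    vars <- all.vars(formula)[-1]
    for (v in vars) d[[v]] <- as.numeric(scale(d[[v]]))
  }
  m <- stats::lm(formula, data = d)
  if (any(is.na(stats::coef(m))))
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(m))[is.na(stats::coef(m))], collapse = ", "))
  s <- summary(m)
  rmse <- sqrt(mean(stats::residuals(m)^2))
  rel <- 100 * rmse / mean(d$sdi_max)
  cf <- stats::coef(m)
  pba_opt <- NA_real_
  quad <- grep("\\^2", names(cf))
  if (length(quad) == 1L && cf[quad] < 0 && !standardize) {
    lin_name <- sub("^I\\((.*)\\^2\\)$", "\\1", names(cf)[quad])
    if (lin_name %in% names(cf)) pba_opt <- -cf[lin_name] / (2 * cf[quad])
  }
  structure(list(coefficients = cf, se = s$coefficients[, 2],
                 sigma_e = s$sigma, rmse = rmse, rel_rmse = rel,
                 bic = stats::BIC(m), r2 = s$r.squared,
                 pba_optimum = unname(pba_opt), n_obs = nrow(d), model = m),
            class = "capacity_model")
}

#' @export
print.capacity_model <- function(x, ...) {
  cat("Carrying-capacity model:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  RMSE = %.1f (%.1f%% of mean)  R2 = %.3f  BIC = %.1f\n",
              x$rmse, x$rel_rmse, x$r2, x$bic))
  if (is.finite(x$pba_optimum))
    cat(sprintf("  implied PBA optimum: %.1f%%\n", x$pba_optimum))
  invisible(x)
}
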