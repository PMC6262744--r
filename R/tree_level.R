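## Tree-level (Ducey-Knapp) strategy: additive stand-density covariates
## from tree lists and a 95th-percentile mixed quantile fit of the unit
## constraint alpha0 x0 + alpha1 x1 + eps = 1.

#' Compute tree-level density-index covariates
#'
#' For each plot-occasion,
#' \eqn{x_0 = \sum EF (d/d_{ref})^{1.6}/100} and
#' \eqn{x_1 = \sum EF \cdot SG (d/d_{ref})^{1.6}/100}
#' (hundreds of metric SDI units at the reference diameter, default
#' 25.4 cm), so that a uniform stand at the reference diameter has
#' \eqn{x_0 = N/100}. `sg_bar` is the basal-area-weighted mean specific
#' gravity (set `sg_weight = "arithmetic"` for the unweighted mean).
#'
#' @param trees tree list with `plot_id`, `occasion`, `d_cm`, `ef`, `sg`.
#' @param d_ref reference diameter (cm).
#' @param exponent Reineke exponent.
#' @param sg_weight `"basal_area"` (default) or `"arithmetic"`.
#' @return data.frame `plot_id`, `occasion`, `x0`, `x1`, `sg_bar`.
#' @export
compute_ducey_covariates <- function(trees, d_ref = 25.4, exponent = 1.6,
                                     sg_weight = c("basal_area", "arithmetic")) {
  sg_weight <- match.arg(sg_weight)
  if (is.null(trees) || nrow(trees) == 0L) stop("no trees")
  if (!"sg" %in% names(trees) || any(!is.finite(trees$sg)))
    stop("specific gravity (sg) missing; supply a species-default table")
  if (any(trees$sg <= 0 | trees$sg >= 1.5)) stop("specific gravity out of range")
  key <- interaction(trees$plot_id, trees$occasion, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    tl <- trees[key == k, , drop = FALSE]
    sz <- (tl$d_cm / d_ref)^exponent
    ba <- tl$ef * tl$d_cm^2
    sgb <- if (sg_weight == "basal_area") sum(ba * tl$sg) / sum(ba) else mean(tl$sg)
    data.frame(plot_id = tl$plot_id[1L], occasion = tl$occasion[1L],
               x0 = sum(tl$ef * sz) / 100,
               x1 = sum(tl$ef * tl$sg * sz) / 100,
               sg_bar = sgb, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit the tree-level frontier (S-T-LME)
#'
#' Fits the unit constraint \eqn{1 = \alpha_0 x_0 + \alpha_1 x_1 + u_i + \epsilon}
#' (no intercept) as a 0.95-quantile mixed model with a plot random
#' intercept, reusing the asymmetric-Laplace marginal-likelihood machinery
#' of the static quantile strategy.
#'
#' @param covariates data.frame from [compute_ducey_covariates()].
#' @param tau quantile (default 0.95).
#' @param nodes Gauss-Hermite nodes.
#' @param var_u0 set 0 to suppress the random intercept; `NULL` estimates it.
#' @param restarts jittered optimizer restarts.
#' @return object of class `tree_fit` with `alpha0`, `alpha1`, SEs,
#'   `var_u0`, `loglik`.
#' @export
fit_tree_level_frontier <- function(covariates, tau = 0.95, nodes = 15L,
                                    var_u0 = NULL, restarts = 5L) {
  stopifnot(all(c("plot_id", "x0", "x1") %in% names(covariates)))
  if (nrow(covariates) < 10L) stop("need >= 10 plot-occasions")
  ratio <- covariates$x1 / covariates$x0
  if (stats::sd(ratio) < 1e-8)
    stop("x0 and x1 are collinear (all specific gravities equal); ",
         "fit the single-covariate reduction on x0 instead")
  X <- cbind(x0 = covariates$x0, x1 = covariates$x1)
  y <- rep(1, nrow(covariates))
  f <- ald_mixed_fit(y, X, covariates$plot_id, tau, nodes = nodes,
                     fix_var_u0 = var_u0, restarts = restarts)
  structure(list(alpha0 = unname(f$beta[1]), alpha1 = unname(f$beta[2]),
                 se_alpha0 = f$se_beta[1], se_alpha1 = f$se_beta[2],
                 var_u0 = f$sd_u0^2, sigma_ala = f$sigma, tau = tau,
                 loglik = f$loglik,
                 plot_effects = data.frame(plot_id = names(f$modes),
                                           u0 = unname(f$modes),
                                           stringsAsFactors = FALSE),
                 n_obs = nrow(covariates)),
            class = "tree_fit")
}

#' Maximum density from the tree-level fit
#'
#' \eqn{N_{max} = 100 / (\alpha_0 + \alpha_1 \overline{SG})}: the stems/ha a
#' uniform stand at the reference diameter can hold given the plot's mean
#' specific gravity.
#'
#' @param fit a `tree_fit`, or a numeric vector c(alpha0, alpha1).
#' @param sg_bar plot mean specific gravity (vectorized).
#' @return stems/ha.
#' @examples
#' nmax_from_tree_fit(c(0.1, 0), 0.5)   # 1000
#' @export
nmax_from_tree_fit <- function(fit, sg_bar) {
  a <- if (inherits(fit, "tree_fit")) c(fit$alpha0, fit$alpha1) else fit
  denom <- a[1] + a[2] * sg_bar
  if (any(denom <= 0)) stop("alpha0 + alpha1 * sg_bar must be positive")
  100 / denom
}

#' @export
print.tree_fit <- function(x, ...) {
  cat(sprintf("Tree-level density-index frontier (tau = %.2f):\n", x$tau))
  cat(sprintf("  1 = %.4f x0 %+.4f x1   (SE %.4f, %.4f)\n",
              x$alpha0, x$alpha1, x$se_alpha0, x$se_alpha1))
  cat(sprintf("  var(u0) = %.4g  logLik = %.2f\n", x$var_u0, x$loglik))
  invisible(x)
}
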