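## Plot-level stand variables and structural summaries from tree lists.

#' Default primary-species codes
#'
#' Codes treated as the primary (pioneer) species when computing the
#' percentage of primary-species basal area (PBA). Defaults to the three
#' *Nothofagus* species of the south-central Chilean roble-rauli-coigue
#' forest type.
#'
#' @export
primary_species_default <- c("NOB", "NAL", "NDO")

#' Compute plot-level stand variables from a tree list
#'
#' Aggregates a single plot-occasion tree list into stems per hectare (N),
#' quadratic mean diameter (dg), basal area (G) and the percentage of basal
#' area in the primary species (PBA). Each tree enters with its expansion
#' factor (trees/ha represented by the measured tree), so
#' \eqn{N = \sum EF}, \eqn{G = \sum EF \cdot (\pi/40000) d^2},
#' \eqn{dg = \sqrt{\sum EF d^2 / \sum EF}} and PBA is the primary-species
#' share of G (percent).
#'
#' @param trees data.frame with columns `plot_id`, `occasion`, `d_cm`,
#'   `species`, `ef` (expansion factor, trees/ha) and optionally `sg`
#'   (specific gravity).
#' @param primary_species character vector of species codes counted as
#'   primary when computing PBA.
#' @return one-row data.frame with `plot_id`, `occasion`, `n_ha`, `dg_cm`,
#'   `g_m2ha`, `pba_pct`.
#' @examples
#' tl <- data.frame(plot_id = "p1", occasion = 0L,
#'                  d_cm = c(10, 20), species = c("NOB", "LAU"),
#'                  ef = c(1, 1))
#' compute_stand_variables(tl)
#' @export
compute_stand_variables <- function(trees, primary_species = primary_species_default) {
  if (is.null(trees) || nrow(trees) == 0L) stop("no trees")
  req <- c("plot_id", "occasion", "d_cm", "species", "ef")
  miss <- setdiff(req, names(trees))
  if (length(miss)) stop("tree list missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(trees$plot_id)) != 1L || length(unique(trees$occasion)) != 1L)
    stop("tree list must belong to a single plot-occasion")
  d <- trees$d_cm
  ef <- trees$ef
  if (any(!is.finite(d)) || any(d <= 0)) stop("non-positive or missing diameter")
  if (any(!is.finite(ef)) || any(ef <= 0)) stop("non-positive expansion factor")
  ba <- (pi / 40000) * d^2          # m^2 per tree
  n_ha <- sum(ef)
  g <- sum(ef * ba)
  dg <- sqrt(sum(ef * d^2) / n_ha)
  prim <- trees$species %in% primary_species
  pba <- 100 * sum(ef[prim] * ba[prim]) / g
  data.frame(plot_id = trees$plot_id[1L], occasion = trees$occasion[1L],
             n_ha = n_ha, dg_cm = dg, g_m2ha = g, pba_pct = pba,
             stringsAsFactors = FALSE)
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum_s p_s \ln p_s} in nats, over species with positive
#' abundance. Invariant to rescaling of the abundances.
#'
#' @param abundance non-negative numeric vector of species abundances
#'   (counts, densities or proportions), optionally named.
#' @return Shannon index in nats.
#' @examples
#' shannon_index(c(1, 1))        # ln 2
#' shannon_index(c(.4, .3, .2, .1))
#' @export
shannon_index <- function(abundance) {
  if (length(abundance) < 1L) stop("need at least one species")
  if (any(!is.finite(abundance)) || any(abundance < 0))
    stop("abundances must be finite and non-negative")
  tot <- sum(abundance)
  if (tot <= 0) stop("all abundances are zero")
  p <- abundance[abundance > 0] / tot
  -sum(p * ln(p))
}

#' Diameter-distribution summaries
#'
#' Expansion-factor-weighted minimum, maximum, median, standard deviation,
#' coefficient of variation (percent) and skewness of the breast-height
#' diameters of a tree list. Expansion factors act as frequency weights.
#' Skewness is the weighted third standardized moment with the population
#' (biased) denominator by default.
#'
#' @param trees data.frame with columns `d_cm` and `ef`.
#' @param bias logical; if `TRUE` (default) moments use the population
#'   (weight-sum) denominator, otherwise small-sample-corrected sd.
#' @return data.frame with `d_min`, `d_max`, `d_median`, `d_sd`, `d_cv`,
#'   `d_skew`. Statistics whose preconditions (>= 2 trees for sd/cv, >= 3
#'   for skewness) fail are `NA`; with all diameters equal skewness is 0.
#' @export
diameter_distribution_stats <- function(trees, bias = TRUE) {
  d <- trees$d_cm
  w <- trees$ef
  stopifnot(length(d) == length(w), all(w > 0))
  n <- length(d)
  out <- data.frame(d_min = NA_real_, d_max = NA_real_, d_median = NA_real_,
                    d_sd = NA_real_, d_cv = NA_real_, d_skew = NA_real_)
  if (n < 1L) return(out)
  out$d_min <- min(d)
  out$d_max <- max(d)
  out$d_median <- weighted_median(d, w)
  if (n < 2L) return(out)
  W <- sum(w)
  mu <- sum(w * d) / W
  v <- sum(w * (d - mu)^2) / if (bias) W else (W - 1)
  out$d_sd <- sqrt(v)
  out$d_cv <- if (mu > 0) 100 * out$d_sd / mu else NA_real_
  if (n < 3L) return(out)
  if (v == 0) {
    out$d_skew <- 0
  } else {
    out$d_skew <- (sum(w * (d - mu)^3) / W) / v^1.5
  }
  out
}

## Weighted median with frequency weights: smallest d whose cumulative
## weight reaches half the total.
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1L]
  if (isTRUE(all.equal(cw[i], 0.5)) && i < length(x)) (x[i] + x[i + 1L]) / 2 else x[i]
}

#' Site covariate summary for a plot
#'
#' Combines a tree list's diversity and diameter-structure summaries with
#' supplied topographic and bioclimatic covariates into the per-plot record
#' used by the carrying-capacity model.
#'
#' @param trees tree list (one plot-occasion) with `species`, `ef`, `d_cm`.
#' @param site optional one-row data.frame of site variables (e.g.
#'   `elevation`, `aspect`, `slope`, `bio1` ... `bio19`); carried through.
#' @return one-row data.frame with `plot_id`, `shannon`, `richness`, the
#'   diameter statistics and any supplied site columns.
#' @export
site_covariates <- function(trees, site = NULL) {
  ab <- tapply(trees$ef, trees$species, sum)
  out <- data.frame(plot_id = trees$plot_id[1L],
                    shannon = shannon_index(as.numeric(ab)),
                    richness = length(ab),
                    stringsAsFactors = FALSE)
  out <- cbind(out, diameter_distribution_stats(trees))
  if (!is.null(site)) {
    site <- site[, setdiff(names(site), names(out)), drop = FALSE]
    out <- cbind(out, site)
  }
  out
}

#' Validate a plot-measurement table
#'
#' Checks the long-format plot table (one row per plot-occasion) for
#' required columns, positive N/dg/G, PBA within [0, 100], and flags plots
#' whose dg decreases between consecutive occasions. Where all of N, dg and
#' G are present, the identity \eqn{G = (\pi/40000) dg^2 N} is checked.
#'
#' @param plots data.frame with columns `plot_id`, `occasion`, `n_ha`,
#'   `dg_cm`, and optionally `g_m2ha`, `pba_pct`, `area_m2`.
#' @param tol relative tolerance for the G identity check.
#' @return the validated table, with attribute `"issues"`: a character
#'   vector describing row-level problems (empty when clean).
#' @export
validate_plot_table <- function(plots, tol = 1e-6) {
  req <- c("plot_id", "occasion", "n_ha", "dg_cm")
  miss <- setdiff(req, names(plots))
  if (length(miss)) stop("plot table missing columns: ", paste(miss, collapse = ", "))
  issues <- character(0)
  bad <- !is.finite(plots$n_ha) | plots$n_ha <= 0 |
    !is.finite(plots$dg_cm) | plots$dg_cm <= 0
  if (any(bad)) issues <- c(issues, sprintf("row %d: non-positive N or dg", which(bad)))
  if ("pba_pct" %in% names(plots)) {
    bp <- is.finite(plots$pba_pct) & (plots$pba_pct < 0 | plots$pba_pct > 100)
    if (any(bp)) issues <- c(issues, sprintf("row %d: PBA outside [0, 100]", which(bp)))
  }
  if ("g_m2ha" %in% names(plots)) {
    g_id <- (pi / 40000) * plots$dg_cm^2 * plots$n_ha
    ok <- !is.finite(plots$g_m2ha) | abs(plots$g_m2ha - g_id) <= tol * pmax(g_id, 1)
    if (any(!ok))
      issues <- c(issues, sprintf("row %d: G inconsistent with dg and N", which(!ok)))
  }
  for (pid in unique(plots$plot_id)) {
    sub <- plots[plots$plot_id == pid, , drop = FALSE]
    sub <- sub[order(sub$occasion), , drop = FALSE]
    if (nrow(sub) > 1L && any(diff(sub$dg_cm) < 0))
      issues <- c(issues, sprintf("plot %s: dg decreases between occasions", pid))
  }
  attr(plots, "issues") <- issues
  plots
}
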