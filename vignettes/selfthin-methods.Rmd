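---
title: "Estimating self-thinning frontiers: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating self-thinning frontiers: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`selfthin` estimates the self-thinning frontier — the upper boundary of the
size–density scatter of forest plots — and the site carrying capacity it
implies, by seven strategies that differ in data source (single-visit
"static" plots, remeasured "dynamic" plots, or tree lists) and in
statistical model. This vignette records the models, their assumptions, the
numerical choices, and the design decisions taken where the methodology was
genuinely open.

## The frontier and carrying capacity

All site-level strategies work on the log scale of Reineke's rule,
$\ln N = b_0 + b_1 \ln d_g$, with $N$ stems/ha and $d_g$ the quadratic mean
diameter (cm). Carrying capacity is summarized as the maximum stand density
index, the frontier evaluated at a base diameter:
$SDI_{max} = \exp(b_0 + b_1 \ln d_{base})$, with $d_{base} = 25.4$ cm by
default (configurable). Natural logarithms are used throughout, asserted in
a single shared transform.

## Static strategies

**S-P-LME.** A random-coefficient Reineke model,
$\ln N_{ij} = (\beta_0 + u_{0i}) + (\beta_1 + u_{1i}) \ln d_{g,ij} + e_{ij}$,
fitted by maximum likelihood with `nlme`. ML rather than REML is used for
*every* strategy so BIC values are comparable across models with different
fixed-effect structures. When the random-slope covariance degenerates
(typical when most plots contribute one observation) the model falls back
to a random intercept with a warning. The self-thinning line shifts the
intercept to the upper bound of its 95% confidence interval,
$b_0 = \hat\beta_0 + 1.96\,SE(\hat\beta_0)$; the conventional 1.96
multiplier is kept verbatim, with an exact $t$ quantile available by
argument.

**S-P-LQMM.** The tau-th conditional quantile of $\ln N$ given $\ln d_g$
with a Gaussian plot random intercept. The fit maximizes a marginal
likelihood whose kernel is the asymmetric Laplace density — minus its log is
the quantile check loss — integrating the random effect by Gauss–Hermite
quadrature (15 nodes by default; the quadrature dimension is one, so node
count is cheap to raise). Because the ALD log-likelihood is only piecewise
smooth, a finite-difference Hessian is unreliable; standard errors use the
outer product of the per-plot score vectors (BHHH), which matched the
empirical sampling variance closely in calibration runs, and a
plot-resampling bootstrap is available. The frontier quantile defaults to
$\tau = 0.95$; `select_quantile()` fits a candidate set and picks the tau
with the smallest summed coefficient sampling variance. With the
random-intercept variance forced to zero the fit reduces to plain quantile
regression: that path minimizes the pinball loss by iteratively reweighted
least squares, a Nelder–Mead polish, and a final vertex refinement (an
exact solution interpolates $p$ observations), and is tested to 1e-4
against an $O(n^2)$ basis-enumeration oracle.

**S-P-SFMM.** A stochastic frontier: $\ln N = X\beta + w_i + V - U$ with
Gaussian noise $V$, half-normal inefficiency $U \ge 0$ (the one-sided gap
below the frontier) and a Gaussian plot intercept $w_i$. The composed-error
density $(2/\sigma)\,\phi(\varepsilon/\sigma)\,\Phi(-\varepsilon\lambda/\sigma)$,
$\sigma^2 = \sigma_u^2 + \sigma_v^2$, $\lambda = \sigma_u/\sigma_v$, is
integrated over $w_i$ by Gauss–Hermite quadrature; simulated ML with
antithetic draws is provided as an alternative since the original tooling
for this model does not document its integration method. The frontier
$X\hat\beta$ is itself the self-thinning line — no shift. When
$\hat\sigma_u \to 0$ the model collapses to the Gaussian mean model whose
implied mean line (frontier lowered by $E[U] = \sigma_u\sqrt{2/\pi}$)
equals OLS; tests check that reduction because $\hat\sigma_u$ itself
converges slowly at the boundary.

**S-T-LME.** The tree-level density-index constraint
$1 = \alpha_0 x_0 + \alpha_1 x_1 + u_i + \epsilon$ at the 95th percentile,
reusing the ALD machinery with no intercept. The printed form of the index
is typographically inconsistent in the source material; the package adopts
$x_0 = \sum EF (d/25.4)^{1.6}/100$ and
$x_1 = \sum EF \cdot SG\,(d/25.4)^{1.6}/100$, which makes the capacity
formula $N_{max} = 100/(\alpha_0 + \alpha_1\overline{SG})$ exact for a
uniform stand at the 25.4 cm reference diameter (both constants are
arguments). $\overline{SG}$ defaults to the basal-area-weighted mean
specific gravity, with the arithmetic mean available, since only an
"average" is specified. The random effect is placed on the intercept of the
constraint; placing it on a coefficient was the other defensible reading.

## Dynamic strategies

**D-P-LME.** The mortality ODE $dN/dd_g = -e^{\beta_0} d_g^{\beta_1}
N^{\beta_2}$ (the sign convention makes mortality explicit; $\beta_1$
exponentiates $d_g$ and $\beta_2$ exponentiates $N$) has the exact solution
$$\ln N_1 = \frac{1}{1-\beta_2}\ln\Big[N_0^{1-\beta_2} +
e^{\beta_0}\tfrac{1-\beta_2}{\beta_1+1}\big(d_{g0}^{\beta_1+1}-d_{g1}^{\beta_1+1}\big)\Big],$$
fitted to consecutive-occasion transitions with Gaussian residuals.
Candidate random-effect placements $\{\beta_0\}, \{\beta_1\}, \{\beta_2\}$
and all three are compared by BIC. Single-parameter placements are fitted
by *exact* marginal ML (Gauss–Hermite over the plot effect): the
linearization used by generic nonlinear mixed fitters was found to bias
$\beta_2$ by a few percent at 40 plots, which recovery tests resolve. The
three-effect variant, a 3-D integral, uses the linearized `nlme` fit and is
flagged as such. Proposals that imply extinction before the observed
$d_{g1}$ are handled by clamping the bracket (a penalized objective), not
by failing. On the admissible domain ($\beta_2 > 1$, increasing $d_g$) the
bracket is in fact always positive — density decays asymptotically, never
to zero — so the clamp is purely a numerical guard. The self-thinning line
is the ODE's attractor: slope $(1+\beta_1)/(1-\beta_2)$, intercept
$[\beta_0 + \ln(\beta_2-1) - \ln(\beta_1+1)]/(1-\beta_2)$, verified against
late segments of numerically integrated trajectories.

**D-P-NBME.** Deaths between occasions as negative-binomial counts with log
link $\ln\mu = \beta_0 + u_{0i} + \beta_1\ln d_{g0} + \beta_2\ln N_0 +
\ln\Delta d_g$ and $\mathrm{Var} = \mu + \mu^2/\theta$; the $\ln\Delta d_g$
term is a fixed offset. Fitting uses `glmmTMB` (nbinom2 implements exactly
this variance function). Per-hectare mortality is converted to plot counts
by `round(delta_n * area / 10^4)` — the NB likelihood needs integers — and
the area ratio enters as a second offset so coefficients stay on the
per-hectare scale. The line again comes from the attractor formulas.

**D-P-NLME.** The first-measurement trajectory predicts $\ln d_g$ from
$\ln N$ with a deviation term anchored at the plot's first measurement:
$$\ln d_g = \alpha_0 + \alpha_1 \ln N -
\frac{(\alpha_0\alpha_2)^2}{\alpha_0 + \alpha_1\ln N_{1st} - \ln d_{g,1st}}
\, e^{-\alpha_3(\ln N_{1st} - \ln N)} .$$
The printed grouping of this expression is ambiguous; the adopted reading
(squared numerator over the first-measurement gap) is isolated in one
function so an alternative is a one-line change. Two consequences of the
structure matter for fitting: $\alpha_2$ enters only squared, so only its
magnitude is identified; and the first measurement is the *conditioning
anchor*, whose deviation from the curve is the plot's own frontier gap
rather than noise — it is therefore excluded from the fitted responses
(including it provably biases all parameters; the exclusion restores exact
recovery on noise-free data). A plot random intercept on $\alpha_0$ is
fitted by `nlme`, with a convergence guard that falls back to nonlinear
least squares when the mixed fit leaves the least-squares basin. The line
inverts the Reineke part: slope $1/\alpha_1$, intercept $-\alpha_0/\alpha_1$.

## Comparison and capacity modelling

Plot-level $SDI_{max}$ uses predicted random effects where a strategy has
them (for the ODE strategies a plot effect $u$ on $\beta_0$ shifts the
attractor intercept by $u/(1-\beta_2)$); population lines are reported
separately, and both the shifted and unshifted intercepts are emitted since
printed results elsewhere do not state which convention they use. The
strategies are compared in a one-way layout by Scheffé's test — every
pairwise contrast against $\sqrt{(k-1)F_{\alpha;k-1,N-k}}\cdot SE$ — which
is already simultaneous, so no further multiplicity correction is added.
Letters come from the insert-and-absorb compact-letter-display algorithm.
Capacity is then regressed on covariates: the 19 bioclim variables are
screened singly by BIC, and the default model uses Shannon diversity,
bio14 (precipitation of the driest month, mm) and PBA plus PBA² (the
share of basal area in the primary species, a successional proxy; PBA is
defined on basal area). A negative quadratic implies an optimum PBA,
reported as $-\theta_{PBA}/(2\theta_{PBA^2})$; note this ratio estimator
carries $O(1/n)$ bias, so its tests check confidence-interval calibration,
not strict unbiasedness. Fit quality is summarized by the relative RMSE,
$100\cdot RMSE/\overline{SDI_{max}}$.

## The synthetic plot network

`simulate_network()` generates the study conditions every fit is tested
under: 130 plots, 20% remeasured (3 occasions), areas 500–10,000 m²,
trees with $d \ge 5$ cm, a generating frontier $\ln N = 12 - 1.5\ln d_g$
and ODE parameters $(\ln 1.5 - 12,\ 0.5,\ 2)$ chosen so the dynamic
attractor coincides with the static frontier.

* **Static plots** scatter below their plot-specific frontier with a
  truncated-exponential gap (mean 0.25, range [0.05, 1.0] on the log
  scale) — a one-sided generative model that makes the 0.95 quantile
  estimable. The stems/ha marginals are constrained to the envelopes
  [330, 3580] (static, $d_g$ 13.7–48.1 cm) and [670, 4680] (dynamic),
  read as the sampling envelope of a network targeting closed-canopy
  secondary stands; the gap distribution is truncated per plot to respect
  them. This makes the gap mildly size-dependent, so frontier-recovery
  properties are checked at a configuration with non-binding envelopes.
* **Dynamic plots** evolve by negative-binomial death counts whose mean is
  the Euler step of the ODE ($\theta = 2$), on the integer count scale of
  the plot area, with lognormal $d_g$ increments of 2–6 cm per period.
  Remeasured permanent plots re-tally the same stems, so dynamic densities
  are treated as census-exact while single-visit static plots carry
  lognormal measurement noise (sd 0.04, truncated at 2.5 sd).
* **Tree lists** draw Weibull(2.3) diameters rescaled to the exact
  quadratic mean (clamped at the 5-cm threshold, reproducing plot N and
  $d_g$ to well under 1%), with a five-species pool (three primary
  *Nothofagus*-type codes, specific gravities 0.42–0.58) whose mix matches
  a Beta-distributed target PBA on [40, 100]%.
* **Covariates**: topography and 19 bioclim variables drawn uniformly in
  plausible south-central-Chilean ranges; the plot frontier offset is
  linked to Shannon diversity (+0.06 per nat), standardized bio14 (+0.06)
  and a concave quadratic in PBA with optimum 50% (−0.05 at the extremes),
  plus N(0, 0.05) residual — so capacity covaries positively with
  diversity and dry-season precipitation, and peaks at mixed composition.
  Setting the effects to zero decouples covariates from capacity.
* A single master seed spawns per-component streams; regeneration is
  byte-identical.

The generator emulates marginal structure, hierarchy and the frontier
geometry. It does **not** emulate spatial autocorrelation, correlated real
climate surfaces, individual-tree growth or ingrowth, species–site
interactions, or irregular measurement intervals — so passing tests
establish the estimators' statistical correctness under the assumed
models, not robustness to those features of real data. On the default
network the dynamic transitions cluster along the attractor, which leaves
the two ODE exponents close to ridge-unidentified — the dynamic strategies'
lines are accordingly erratic there, a behavior real remeasured networks
share; their recovery tests therefore use broader transition designs.

## Problem sizes and numerical settings

Recovery tests run 25–40 replicates per fitter at 100–250 units (the
sizes are stated in each test); quantile calibration uses 1000
observations; the Scheffé familywise error simulation uses 10,000
replicates of seven equal-mean groups; screening power uses 200
replicates at 60 plots. Optimizers are quasi-Newton with five jittered
restarts (internal fixed seeds, caller RNG state preserved) and a
Nelder–Mead polish, tolerance 1e-10–1e-12; Gauss–Hermite uses 15 nodes;
CSV output serializes floats at 17 significant digits for lossless round
trips. Plot areas are drawn uniformly on the stated range and then
adjusted to the nearest tree count so expansion factors are exactly
consistent with density.

## Known limitations

* The three-random-effect density variant relies on a linearized
  likelihood; its BIC is only approximately comparable to the exact-ML
  single-effect variants.
* BHHH standard errors assume a correctly specified likelihood; under
  misspecification a sandwich would be needed.
* The tree-level strategy needs specific gravities; there is no trait
  imputation beyond a species table.
* Attractor-based lines require $\hat\beta_2 > 1$ and $\hat\beta_1 > -1$;
  small dynamic samples can land outside that domain, in which case the
  strategy's line is reported as failed rather than extrapolated.
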