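---
title: "Models and methods behind ecoeff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ecoeff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoeff)
```

ecoeff measures the eco-efficiency of regional agricultural production —
output per unit of input once carbon emissions are counted as a bad — and
then asks where that efficiency clusters, what moves it, and where it is
heading.  This vignette is the package's own account of each model, its
assumptions, the tunable parameters, and the numerical choices that a
maintainer would otherwise have to reverse-engineer from the code.

## 1. The data model

Everything operates on a tidy region-year panel: one row per region-year
with inputs (capital stock, 1e8 yuan; labour, 1e4 persons; energy, 1e4 tce),
a desirable output (GDP, 1e8 yuan), an undesirable output (carbon, 1e4 t),
and free-form covariates.  `read_panel()` enforces the two integrity rules
every downstream stage relies on: unique (region, year) keys (violations are
an error, not a warning, because duplicated keys silently corrupt transition
counts and panel likelihoods) and numeric parses for required roles (rows
that fail are dropped loudly, with row numbers).  Spatial structure is an
`eco_weights` matrix — nonnegative, zero diagonal — read from dense CSV or
GAL neighbour lists; GAL input is symmetrized, since contiguity is an
undirected relation.  Missing covariate cells pass through untouched; each
stage documents whether it drops or rejects them (the regression stages
require balanced, complete panels and say so).

Descriptive summaries (`summarize_panel()`) use the sample (n−1) standard
deviation and define the "annual growth" of a variable as the geometric-mean
growth rate of its cross-region yearly total, in percent.  Published
descriptive tables for this kind of data are not always internally
consistent (the case-study table bundled here prints a maximum below its
mean in one narrative reading); the summaries implement the formulas and
make no attempt to reproduce any specific printed cell.

## 2. Efficiency with an undesirable output

The slack-based measure evaluates each region-year (a decision-making unit,
DMU) against the best-practice frontier formed by its peers:

$$\rho_0=\min_{\lambda,s}\ \frac{1-\frac1m\sum_i s_i^-/x_{i0}}
{1+\frac1s\left(\sum_r s_r^g/y^g_{r0}+\sum_r s_r^b/y^b_{r0}\right)}$$

subject to $x_0 = X\lambda + s^-$, $y^g_0 = Y^g\lambda - s^g$,
$y^b_0 = Y^b\lambda + s^b$, $\sum_k\lambda_k = 1$ (variable returns to
scale), all slacks nonnegative.  Carbon enters through reduction slacks
$s^b$ by default (`bad_mode = "output"`); treating it as an input
(`bad_mode = "input"`) is offered because the accounting treatment of bads
is a modelling choice, not a mathematical consequence.  The fractional
program is solved exactly through the Charnes–Cooper transformation, which
turns it into a linear program in scaled variables.

Super-efficiency re-scores units that reach 1: the unit is removed from its
own reference set and projected onto the frontier of the rest, with
undesirable outputs allowed to rise toward peer levels (input-like
behaviour); the resulting score is $\ge 1$ and strictly ranks efficient
units wherever the optima differ.  Degenerate alternate optima are resolved
by a lexicographic second stage that fixes the score and maximizes total
normalized slack, so reported slacks are the maximal ones supporting the
score.

The linear programs are solved by an internal dense two-phase primal
simplex with Bland's anti-cycling rule.  SBM programs are heavily
degenerate (many zero right-hand sides, frequent ties), which is what
Bland's rule is for; with tens of variables per program, pivot-rule
efficiency is irrelevant.  The tests check the solver against an
independent route: direct minimization of the fractional objective over the
$\lambda$-simplex, where slacks are closed-form given $\lambda$.

`frontier_distances()` reports, per year, mean scores against the
contemporaneous frontier ($D_t$, same-year peers), the sequential frontier
($D_o$, all years up to the current one), and the global frontier ($D_g$,
all years pooled).  The three labels in published comparisons of "current,
overall and frontier" technologies are ambiguous; this mapping — sequential
for "overall", pooled for the global benchmark — is a recorded package
decision, and the nesting $D_g \le D_o \le D_t$ holds by construction
because the reference sets are nested.

## 3. Spatial autocorrelation and spatial Markov dynamics

Global Moran's I uses the randomization-assumption closed-form variance by
default, matching the single z/p pair per year that applied studies report.
The permutation alternative reshuffles values across regions under a fixed
seed and returns a two-sided rank p-value computed from deviations around
the *permutation mean*: the null distribution of I is centred at
$-1/(n-1)$, not zero, and absolute deviations around zero would
systematically inflate two-sided p-values (we measured a factor-two
inflation on a 25-node lattice before centring).  Both p-values are
two-sided; a one-sided convention cannot reproduce a positive z with a
significant "negative" year anyway, so the package simply computes.

Efficiency dynamics are discretized into k = 4 quantile states by default
(quartiles over the pooled panel; per-year binning is available since the
pooling convention is rarely stated in applied work), with boundary values
assigned to the lower state.  Transition matrices count region moves over
consecutive year pairs only; rows with no observed origin are reported as
`NA` rather than zero-filled, so "every observed row sums to one" is an
enforced invariant, not an accident.  The spatial Markov variant stratifies
transitions by the origin-year state of the spatial lag (classified on the
same bins, which is why `discretize_states()` exposes its breaks), and the
stratified counts always sum back to the ordinary ones.

## 4. The spatial Durbin panel model

The regression stage estimates
$$y_{it} = \rho\,(Wy_t)_i + x_{it}'\beta + (WX_t)_i'\varphi + \mu_i +
\nu_t + \varepsilon_{it}$$
by concentrated quasi-maximum likelihood.  Two numerical decisions matter:

* **Fixed effects are removed by orthonormal deviation transforms**, not
  dummies or plain within-demeaning.  An orthonormal basis of the space
  orthogonal to the unit vector is applied over time (removing $\mu_i$) and
  over the cross-section (removing $\nu_t$); with row-standardized $W$ the
  cross-sectional transform carries the spatial lag into an
  $(n-1)\times(n-1)$ matrix whose unit eigenvalue is removed, and the
  transformed errors remain exactly iid.  We first implemented the
  dummy-variable estimator and measured its incidental-parameter bias at
  the package's reference design (30 regions, 20 years, $\rho = 0.3$):
  $\hat\rho$ was biased by $-0.18$, with $\hat\varphi$ absorbing
  $\rho\beta$.  The transformation estimator's measured mean bias at the
  same design is below 0.01 on every parameter, and the Wald test below has
  empirical size 0.05.
* **The likelihood is concentrated in $\rho$.**  Given $\rho$, all other
  coefficients are closed-form OLS of $y - \rho Wy$ on the (transformed)
  regressors; the Jacobian term $T^*\sum_i\log(1-\rho\lambda_i)$ uses
  eigenvalues computed once.  $\rho$ is found by bounded scalar search on
  the stability interval with tolerance 1e-8.  The parameter covariance is
  the analytic information matrix of the transformed likelihood.

Effects decomposition follows the partial-derivative view: for regressor k,
$S_k(W) = (I-\rho W)^{-1}(I\beta_k + W\varphi_k)$; the direct effect is the
mean diagonal (own-region impact including spatial feedback), the total
effect the mean row sum, the indirect effect their difference.  Standard
errors simulate $(\rho,\beta,\varphi)$ from the estimated asymptotic normal
(1000 draws by default; fewer than 100 triggers a warning).  The Wald
reductions test $\varphi = 0$ (to SAR) and the common-factor restriction
$\varphi + \rho\beta = 0$ (to SEM, delta method), both $\chi^2$ with df =
number of lagged regressors.  Time-lagged designs ("explanatory variables
lagged by one period") are a data operation, `xlag_periods = 1`, which
shifts regressors within region and shortens the panel accordingly.

Covariates with opaque published names (interval discrimination, STQ, OS,
ES, UR and its square, TI, EE, a "Kalman filter" index) are carried as
ordinary named columns: no filtering recursion is implied by a column name,
and the squared-urbanization regressor is constructed by the caller so the
model never guesses at transformations.

## 5. The stochastic production frontier

The frontier stage fits
$\ln y_{it} = x_{it}'\beta + v_{it} - u_{it}$ with
$v_{it}\sim N(0,\sigma_v^2)$ and time-decaying inefficiency
$u_{it} = e^{-\eta(t-T_i)}u_i$, $u_i \sim N^+(\mu,\sigma_u^2)$, reported in
the $(\sigma^2 = \sigma_u^2+\sigma_v^2,\ \gamma = \sigma_u^2/\sigma^2)$
parameterization.  The per-region likelihood has a closed form (a
one-dimensional truncated-normal convolution); the unit tests verify it —
and the conditional-expectation efficiency predictor
$TE_{it} = E[e^{-u_{it}}\mid\varepsilon_i]$ — against direct numerical
integration to 1e-10.

The translog design has the 15 columns (trend, three log inputs, squares,
trend interactions, pairwise cross terms, intercept) in a fixed order, with
plain products (no ½ factors).  `center = TRUE` evaluates it on logs
centred at geometric means, the standard normalisation that makes
first-order coefficients elasticities at the sample mean; the generator and
estimator use the same centring, so recovery studies are internally
consistent.

Optimization is multi-start L-BFGS-B on transformed parameters
($\log\sigma^2$, $\mathrm{logit}\,\gamma$) with box bounds that keep the
search away from the $\sigma_v\to 0$ region, where the likelihood surface
collapses numerically.  Starts traverse a small $(\gamma,\eta)$ grid; the
default is 5 starts, and the Monte-Carlo harnesses use 1–2 because the
recovery designs are strongly identified.  Restrictions (`mu = 0`,
`eta = 0`, `gamma = 0`) pin parameters for the nested models of the
likelihood-ratio tests; `gamma = 0` collapses to exact OLS.  For variance
parameters on the boundary the LR statistic is referred to the mixed
$\tfrac12\chi^2_{df-1}+\tfrac12\chi^2_{df}$ distribution.  Published LR
tables for this model family are not always reconcilable with any standard
reference distribution (a printed statistic of 1.80 on 15 df marked
significant); the package computes honest statistics and leaves the reader
to draw conclusions.

One identification point shapes the no-inefficiency diagnostic: with $\mu$
free, the null $\sigma_u^2 = 0$ is not testable, because a truncated normal
with large $\mu$ is indistinguishable from added Gaussian noise.  The null
simulation therefore pins $\mu = \eta = 0$ (half-normal, time-invariant).
Under that null $\hat\gamma$ piles on the zero boundary with a positive
tail fed by region-mean sampling noise ($\sigma_v^2/T$); the package's
acceptance harness summarizes "$\gamma \to 0$" by the median (< 0.05) and
mean (< 0.1) over 100 replicates, which is what the estimator actually
delivers at 30 regions × 10 years.

## 6. Grey forecasting and the neural corrector

GM(1,1) fits the accumulated series: with $x^{(1)} = \mathrm{AGO}(x^{(0)})$
and mean sequence $z(t) = (x^{(1)}(t-1)+x^{(1)}(t))/2$, least squares on
$x^{(0)}(t) = -a\,z(t) + u$ gives $(a, u)$, and fitted/forecast values are
restored from the time response
$\hat x^{(1)}(t+1) = (x^{(0)}(1) - u/a)e^{-at} + u/a$ by differencing, with
$\hat x^{(0)}(1) = x^{(0)}(1)$ (zero base-year error by convention, which
published error tables show).  Diagnostics follow the posterior-difference
test: $C = s_2/s_1$ (residual to observed spread) and the small-error
probability $P$, graded on the four literal bands (C strictly below, P
strictly above; grade 4 otherwise), with the base-period residual excluded
since it is zero by construction.  "Average relative error" likewise
averages over $t \ge 2$.

A subtlety documented here because it bounds every exactness claim: the
estimation step is discrete (the mean-sequence equation) while restoration
is continuous (the exponential solution).  On exactly geometric data with
ratio $r$ the least-squares development coefficient is
$\hat a = 2(1-r)/(1+r)$, not $-\log r$; the two agree to $O(a^3)$.
Consequently the grey difference equation is solved *exactly* (zero
regression residual) on geometric data, while restored values and
round-trips of $(a,u)$ through the generator are exact only to the
discrete/continuous mismatch: at the generator's default decay
($a = 0.0034$, a slowly declining 1.5e4-scale aggregate, the regime grey
models are meant for) that is ~3e-9 on $a$ and ~1e-6 relative on $u$ and
the fitted levels.  Nearly-constant series ($|a| < 10^{-12}$) take a
degenerate branch that fits the mean, with a warning.

The back-propagation network is deliberately classical — one sigmoid hidden
layer, linear output, full-batch gradient descent on MSE, min-max
normalization of every feature and target to $[-1,1]$, weights initialized
uniform$(-0.5, 0.5)$ under a seed — so training is bit-reproducible.
Defaults (5 hidden units, learning rate 0.05, 10 000 epochs, target MSE
1e-5) are conventional small-network settings; none are stated in the
literature this follows, so they are tunable arguments.  The hybrid couples
the two: a network is trained on sliding windows (default 3) of past GM
residuals to predict the next residual, and the combined value is GM +
predicted residual, an identity the object maintains elementwise.
Forecasting rolls the residual window forward on the network's own
predictions.  If the grey fit is already exact to 1e-10 the corrector is
the zero function by construction.

## 7. The synthetic provincial panel

`simulate_panel()` is the generative inverse of the frontier model:
log-uniform inputs over ranges matching the order of magnitude of published
provincial descriptive statistics (capital 361–165 425 × 1e8 yuan, labour
245–6 826 × 1e4 persons, energy 310–44 026 × 1e4 tce), a translog frontier
whose default coefficients are the package's reference set, truncated-normal
time-decaying inefficiency, and Gaussian noise.  Carbon is
$c\,\mathrm{energy}^{\kappa}$ with lognormal noise ($c = 5$,
$\kappa = 0.9$, chosen once to land carbon in the published 1e4-t range and
guarantee positivity and monotonicity in energy — no emission-accounting
scheme is implied).  The latent $u_{it}$ and $TE_{it}$ ride along in a
sidecar for recovery studies.  `simulate_sdm_panel()` draws the reduced
form $(I-\rho W)^{-1}(X\beta + WX\varphi + \mu + \nu_t + \varepsilon)$
year by year with iid standard-normal regressors and region/year effect
variances defaulting to 0.1.  `simulate_grey_series()` emits the exact
GM(1,1) restored-value pattern plus optional additive noise; its defaults
($x_1 = 15783$, $a = 0.0034$, $u = 15800$) emulate a smooth, slowly
declining national aggregate of the size the forecaster is applied to.

What the generator deliberately does not emulate: real provincial
magnitudes beyond order of magnitude, spatial correlation in the *inputs*,
measurement error, or unbalanced panels.  Passing recovery tests on these
panels therefore demonstrates estimator correctness under the stated
models, not robustness to real-data pathologies.

Reference Monte-Carlo designs (sizes chosen as the package's standard
recovery studies): spatial Durbin at 30 regions × 20 years, 200 seeds for
recovery and 500 for test size; frontier at 30 × 10 with a Cobb–Douglas
frontier (a valid restriction of the translog that keeps each fit fast and
the design strongly identified), 100 seeds.

## 8. The case-study tables

Three published tables travel with the package as data: organic and
conventional rice yields (kg/mu, 2012–2021), the itemized cost sheet
(RMB/mu) with owner-imputed labour and land rent flagged, and the national
agricultural carbon-sink series with grey and grey-neural simulated values
and printed error columns.  The package recomputes their arithmetic —
integer percentage ratios rounded half-up, column totals, per-period
relative errors — and `cost_consistency()` reports, without overwriting,
the places where the printed tables disagree with their own columns (a
packaging row printing 500 against items 700 vs 0; a printed total
difference of 484 where the columns give 485; a printed 2013 relative error
of 1.35 where the row's own values give 1.30).  The published mean absolute
errors (1.53% and 0.52%) are reproduced exactly from the printed error
columns, which is how those means were evidently formed.  Whether the
parenthetical cash totals exclude imputed items from one column or both is
ambiguous in the source; `exclude_imputed = TRUE` drops them from the
conventional column only, a recorded convention.

## 9. Known limitations

* The DEA solver is pure R; thousands of DMUs per frontier would call for a
  compiled LP backend.
* The SDM stage requires balanced panels and row-standardized weights;
  unbalanced spatial panels are out of scope.
* Super-efficiency under constant returns can be unbounded for extreme
  units; such programs return an `unbounded` status rather than a score.
* The BC92 frontier assumes a common decay rate $\eta$ across regions, and
  the published decay magnitude (η ≈ 0.41 over a decade) implies extremely
  low early-period efficiencies; the estimator handles it, but users should
  sanity-check $TE$ trajectories.
* Forecast intervals are not provided for the grey-neural hybrid; the
  residual network gives point corrections only.
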