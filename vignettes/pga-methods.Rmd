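---
title: "Physiologically guided abundance models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiologically guided abundance models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Surveys of lake fish count individuals caught per deployment of a gear
(a gill net or trap net set for 24 hours). `pgabund` models the count
$C_{ijt}$ for lake $i$, gear $j$, year $t$ as

$$C_{ijt} \sim \mathrm{Poisson}(E_{ijt}\,\theta_j\,\lambda_{it}),$$

where $E_{ijt}$ is sampling effort in net-nights, $\theta_j$ is a
gear-specific catchability multiplier, and $\lambda_{it}$ is relative
abundance — an index assumed proportional to true abundance. The
physiologically guided (PGA) variant couples relative abundance to a
laboratory-informed thermal performance curve $P(\cdot)$:

$$\lambda_{it} = P(T_{it})\,\exp(\mathbf{x}_{it}'\boldsymbol\beta),$$

with $T_{it}$ the 5-year trailing mean of mean July surface water
temperature and $\mathbf{x}_{it}$ the standardized lake covariates
(temperature excluded — it acts only through $P$). Because fish are
poikilotherms, $P$ encodes a hard physiological constraint: performance
rises along a Gaussian limb from the critical thermal minimum
$CT_{min}$ to 1 at the optimum $T_{opt}$, declines quadratically to 0 at
the critical maximum $CT_{max}$, and is exactly 0 above it:

$$P(T) = \begin{cases}
\exp\!\big(-\big(\tfrac{T - T_{opt}}{2\sigma}\big)^2\big) & T \le T_{opt},\\
1 - \big(\tfrac{T - T_{opt}}{T_{opt} - CT_{max}}\big)^2 & T_{opt} < T \le CT_{max},\\
0 & T > CT_{max}.
\end{cases}$$

The Gaussian limb applies to *all* temperatures at or below the optimum,
so the curve is small but not exactly zero at $CT_{min}$:
$P(CT_{min}) = e^{-4} \approx 0.018$ under the derived scale (below).
We follow the piecewise definition literally and document this residual
rather than forcing $P(CT_{min}) = 0$.

The competing **naive** model drops $P$ and instead adds standardized
temperature and its square to $\mathbf{x}_{it}$ — the common
quadratic-response habit in species distribution modelling. It has no
thermal limit: its predicted abundance is positive at any temperature,
which is exactly the behaviour the PGA model is designed to correct when
extrapolating beyond the observed temperature range.

## Thermal traits, their uncertainty, and the integration scheme

Laboratory studies report $T_{opt}$ (usually from growth) and
$CT_{min}/CT_{max}$ (usually loss of equilibrium), but rarely $\sigma$.
The package derives it from the trait means:

$$\sigma = (T_{opt} - CT_{min})/4,$$

placing $CT_{min}$ four Gaussian scale units below the optimum. $\sigma$
is held fixed across curve realizations, computed from the *prior means*
of $T_{opt}$ and $CT_{min}$; a config hook (`sigma_sd` in
`thermal_prior()`) allows a truncated-normal prior on $\sigma$ but is off
by default. $CT_{min}$ itself carries no prior — only its mean enters,
through $\sigma$.

Between-study disagreement in the traits is real and is represented by
independent normal priors on $T_{opt}$ and $CT_{max}$ (means and SDs
supplied per species, e.g. via a YAML config). Rather than letting the
survey likelihood overwhelm these laboratory values — survey temperatures
rarely span a species' tolerable range, so the data cannot identify
$CT_{max}$ — the package integrates numerically over the prior:

1. draw a curve realization $(T_{opt}, CT_{max})$ from the priors,
   jointly rejecting and redrawing any pair with $T_{opt} \ge CT_{max}$
   (rejection keeps the marginals interpretable, unlike conditional
   truncation of one parameter given the other);
2. fit the Bayesian Poisson model by MCMC with that curve held fixed;
3. repeat (100 realizations by default) and pool the tagged posteriors.

With the default chain settings — 3,000 iterations, 2,000 burn-in,
every 5th retained — each realization contributes 200 draws and the
default ensemble aggregates 20,000. Draws are pooled with equal weight;
ordering is fixed by realization index so a fit is bit-reproducible from
its master seed (every chain and the curve sampler receive derived
sub-seeds).

## Priors and identifiability

Coefficients get $\beta_l \sim N(0, 100)$, read as *variance* 100
(SD 10, exposed as `beta_prior_sd`); the notation is ambiguous across
conventions, and SD 100 would be materially flatter, so the choice is
config-exposed. Catchability uses a scaled Dirichlet: $\theta = J\,d$
with $d \sim \mathrm{Dirichlet}(\mathbf{1})$ on the $(J-1)$-simplex, so
$\sum_j \theta_j = J$. Without that constraint the likelihood is flat
along $(\theta, \beta_0) \mapsto (c\theta, \beta_0 - \ln c)$; the
constraint removes the direction (the test suite checks both halves of
this statement). The design matrix always includes an intercept — the
scale of $\lambda$ is then shared between the intercept and $\theta$,
which the constraint resolves.

## Covariate pipeline

Raw inputs are one row per lake-year: July temperature, lake area (ha),
maximum depth (m), Secchi depth (m), and watershed proportions of
developed, agricultural, and wetland cover. The pipeline applies:

* trailing 5-year rolling means (the sample year and four preceding
  years) for temperature and Secchi depth — trailing, not centered,
  because predictors must be computable at sampling time; partial
  windows use the available years;
* $\log_e$ transforms for area and depth, logit transforms for the
  proportions (clamped to $[10^{-3}, 1-10^{-3}]$ first — the boundary
  behaviour is otherwise undefined and the clamp keeps zero-cover
  watersheds finite);
* standardization of every column to mean 0, SD 1, with the training
  means/SDs stored on the design object and reused verbatim for
  scenario matrices.

For the naive design the squared term is computed from the standardized
temperature and then standardized itself, so every column of either
design is on a common scale and scenario reuse of training statistics is
uniform. Warming offsets are applied to temperature in degrees Celsius
*before* any standardization.

## Likelihood floor

A curve realization with a low $CT_{max}$ can place an observed positive
catch above the thermal limit, making that realization's likelihood
$-\infty$ and poisoning the pooled ensemble. Inside likelihood
evaluation only, $P$ is floored at `performance_floor` ($10^{-10}$ by
default). Predictions — performance summaries, percent change,
extinction probabilities — always use the unfloored curve, so
extirpation ($P = 0$ exactly) remains representable.

## MCMC backend and diagnostics

Sampling is delegated to JAGS through `rjags`: a single chain per
realization, initialized at jittered zeros for $\beta$ and near-uniform
$d$, with up to five re-initializations if a chain fails to start. The
sampler is a contract, not the contribution — any correct MCMC targeting
the stated posterior would do; the package requires only correctness and
reproducibility. Per-realization chains are summarized by split-$\hat R$
(the single chain compared across its halves) and effective sample size;
chains with split-$\hat R > 1.05$ are flagged in
`convergence_summary()`, and traces can be exported with
`write_traces()` for visual inspection. Multi-chain $\hat R$ per
realization is deliberately out of scope (one chain per realization,
many realizations).

## Model comparison: PSIS-LOO

`pga_loo()` computes leave-one-out expected log pointwise predictive
density by Pareto-smoothed importance sampling on the pooled draws, each
draw using its own realization's curve. Raw importance log-ratios for
record $n$ are $-\ell_{sn}$; the largest
$M = \lceil\min(0.2S, 3\sqrt S)\rceil$ ratios are replaced by expected
order statistics of a generalized Pareto distribution fitted to their
exceedances (Zhang–Stephens weighted-profile estimator with the weak
shape prior standard in the PSIS literature), truncated at the raw
maximum. The shape diagnostic $\hat k$ is reported per record and values
above 0.7 raise a warning column, not a failure; no moment-matching
refits are attempted. `loo_ic = -2\,\mathrm{elpd}` exactly, and lower is
better. How LOO should interact with the 100-fit integration scheme is
genuinely open; the package treats the pooled 20,000 draws as one
posterior sample, the simplest defensible convention, and exposes the
pointwise matrix for users who prefer another.

## Climate projections

`project(fit, delta_t)` applies a uniform warming offset (0-4 °C in the
usual sweep) to each lake's temperature, holding all other covariates at
current values, and summarizes per lake (most recent sampled year):

* the unfloored performance scalar's posterior mean and central 95%
  interval;
* percent change in relative abundance, computed **per draw** as
  $100(\lambda^{scn}_s - \lambda^{cur}_s)/\lambda^{cur}_s$ and then
  summarized — propagating the joint posterior rather than taking a
  ratio of posterior means. A draw extinct under the scenario
  contributes exactly $-100\%$; a draw already extinct under current
  conditions contributes $-100\%$ if it stays extinct and is excluded
  (and counted) in the rare case a cooling scenario would revive it;
* the posterior probability of extinction: the fraction of draws whose
  realization puts the scenario temperature above $CT_{max}$. Lakes
  with probability > 0.90 are flagged extirpated, and
  `extirpation_census()` tallies flags overall and among currently
  inhabited lakes (those with at least one positive observed catch —
  the data-driven reading of "currently inhabit").

The naive model gets the same percent-change machinery but has no
notion of extinction: `extinction_probability()` refuses naive fits, and
its predicted abundance is strictly positive everywhere. Per-lake
summaries are the primary output; the print method adds the pooled
across-lake mean and range, so both summary conventions are available.

## The synthetic survey generator

`simulate_survey()` emulates the structure of a statewide inland-lake
survey: tens to hundreds of lakes (the real system spans ~1,300), two
gears with catchabilities summing to 2, multi-year sampling, effort of
one net-night per record, and Poisson counts generated exactly from the
model above. Lake-level July temperatures are normal with mean 24 °C and
SD 2.5 °C plus small interannual noise (SD 0.6 °C), emulating a unimodal
20-30 °C statewide distribution; areas and depths are lognormal, land
use/cover proportions beta-distributed, Secchi depth lognormal. Three
trait-prior archetypes (`species_archetype()`) give cold-, cool-, and
warm-water species with optima ordered cold < cool < warm; the exact
numbers are package defaults chosen to be plausible for the
corresponding guilds, documented as such, and not literature estimates.

What the generator does *not* emulate: spatial autocorrelation among
lakes, gear-by-habitat interactions, overdispersion or zero inflation
beyond Poisson, ontogenetic or acclimation effects, and the
process-model provenance of real temperature series. Passing tests on
synthetic data therefore demonstrate correctness of the machinery and
calibration under the stated generative model — not robustness to the
misspecifications real surveys carry.

`truncated_range_experiment()` stages the package's central scientific
contrast: both models are trained only on lakes below a temperature
ceiling (data truncation) and projected under warming that pushes lakes
past the generating $CT_{max}$. The naive model predicts persistence
there; the PGA model's extinction probability rises to 1.

## Numerical choices and degenerate inputs

* Curve sampling rejects jointly and caps total draws at
  `max_tries * n`; hitting the cap reports incompatible priors instead
  of looping.
* Degenerate (zero-SD) trait priors are legal and collapse the ensemble
  to repeated fits of one curve; the test suite uses a
  Kolmogorov–Smirnov check to confirm the pooled ensemble is then
  indistinguishable from one long chain.
* A constant covariate column is an error at standardization time, not
  a silent zero.
* `rolling_mean_5yr` with an empty window is an error; a single
  available year is used as-is.
* PSIS smoothing of an all-equal weight vector returns it unchanged
  with $\hat k = -\infty$; fewer than ~25 draws (tail below 5) is an
  error.
* Chain-length bookkeeping uses integer division; retained draws per
  realization are $(\texttt{n\_iter} - \texttt{n\_burnin})/\texttt{thin}$.

## Problem sizes used in the test suite

The suite exercises reduced but honest configurations chosen to keep a
full run near a quarter hour: ensembles of 2-8 realizations with chains
of 250-1,600 iterations for machinery tests; the calibration study uses
20 replicate surveys of 300 lake-years (100 lakes x 3 years, 2 gears)
with 600 retained draws each; the GLM-limit oracle uses 200 lakes with
the default 3,000-iteration chain; exact leave-one-out refits use 20
records and 4,000-draw chains. Calibration is asserted on the aggregate
binomial count of 95%-interval coverage events across coefficients and
replicates at a 90% floor: with 7 coefficients, requiring every
coefficient separately to clear 18/20 would fail a perfectly calibrated
sampler about 40% of the time by binomial noise alone, while the
aggregate count separates calibrated from miscalibrated samplers
reliably.

## Known limitations

* Poisson observation only: no overdispersion, zero inflation, or
  occupancy layer.
* One chain per realization mirrors the reference scheme; users wanting
  classical multi-chain $\hat R$ should run multiple ensembles with
  different master seeds.
* The curve family is fixed (Gaussian ascent, quadratic decline);
  Sharpe–Schoolfield or beta-function curves are out of scope.
* Thermal traits are static: no acclimation, plasticity, evolution, or
  ontogenetic stage structure.
* Scenario projections shift temperature only; other covariates are
  held at current values, and no dispersal or colonization dynamics are
  modelled.
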