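# pgabund

Climate warming is redistributing cold-blooded species, but the survey
data used to model their abundance rarely span the temperatures a species
can actually tolerate. Purely data-driven models extrapolated beyond the
observed range can then predict comfortable persistence at temperatures
that are physiologically lethal. `pgabund` implements a **physiologically
guided abundance (PGA) model** for multi-gear fish survey counts: a
Bayesian Poisson catch model whose relative-abundance term is scaled by a
laboratory-informed thermal performance curve, so that predictions inherit
a hard critical thermal maximum. It is aimed at quantitative ecologists
and fisheries scientists working with catch-per-unit-effort survey data
and laboratory thermal-tolerance literature.

## The model

Catch $C_{ijt}$ of a species in lake $i$ with gear $j$ in year $t$, with
effort $E_{ijt}$ net-nights:

$$C_{ijt} \sim \mathrm{Poisson}(E_{ijt}\,\theta_j\,\lambda_{it}),
\qquad \lambda_{it} = P(T_{it})\,\exp(\mathbf{x}_{it}'\boldsymbol\beta),$$

where $\theta$ is the gear catchability vector (scaled Dirichlet prior,
$\sum_j \theta_j = J$), $\mathbf{x}_{it}$ are standardized lake
covariates, and $P$ is the thermal performance curve: a Gaussian limb
rising to 1 at the thermal optimum $T_{opt}$, a quadratic decline to 0 at
the critical thermal maximum $CT_{max}$, and 0 beyond, with the Gaussian
scale derived from laboratory traits as
$\sigma = (T_{opt} - CT_{min})/4$. Literature uncertainty in $T_{opt}$
and $CT_{max}$ enters through independent normal priors; the package
integrates over it by sampling curve realizations (truncated to
$T_{opt} < CT_{max}$), fitting the model by MCMC with each curve fixed,
and pooling the posteriors (100 realizations x 200 retained draws =
20,000 draws by default). A **naive** competitor replaces $P$ with
standardized temperature + temperature² in the linear predictor; the two
are compared by PSIS-LOO cross-validation (`loo_ic = -2 elpd`, lower is
better). Warming scenarios (+1 to +4 °C on mean July surface
temperature) yield per-lake percent change in relative abundance,
thermal performance summaries, and — for the PGA model only — posterior
extinction probabilities.

## Worked example

Simulate a cold-water species (optimum 16 °C, critical maximum 24 °C)
surveyed in lakes averaging 24 °C in July — a species already living near
its thermal edge — then fit both models and project +4 °C:

```r
library(pgabund)
sim  <- simulate_survey(n_lakes = 60, n_years = 2, species = "cold",
                        temp_mean = 24, temp_sd = 2.5, seed = 10)
ctrl <- pga_control(n_iter = 1500, n_burnin = 500, thin = 5,
                    n_realizations = 20)
fit  <- pga(sim$catch, sim$covariates, prior = species_archetype("cold"),
            model = "pga", control = ctrl, seed = 20)
fit
#> Physiologically guided Bayesian Poisson abundance model
#>   240 catch records, 120 lake-years, 2 gear(s)
#>   20 curve realizations x 200 retained draws = 4000 aggregated draws
#>
#> Posterior means:
#>       (Intercept)          log_area         log_depth            secchi
#>             1.338             0.593             0.068             0.235
#>   logit_developed logit_agriculture     logit_wetland    theta[gillnet]
#>             0.253            -0.032             0.037             1.253
#>    theta[trapnet]
#>             0.747

project(fit, delta_t = 4)
#> Scenario projection (pga model, +4 degC), 60 lakes
#>   percent change in relative abundance: mean of lake means -97.7% (range -100.0% to -63.6%)
#>   lakes flagged extirpated (P(extinction) > 0.90): 43 (72%)

extirpation_census(project(fit, 4))
#>            subset n_lakes n_flagged pct_flagged
#> 1       all_lakes      60        43    71.66667
#> 2 inhabited_lakes      24         7    29.16667

naive <- pga(sim$catch, sim$covariates, model = "naive", control = ctrl,
             seed = 21)
pga_compare(pga_loo(fit), pga_loo(naive), labels = c("pga", "naive"))
#> PSIS-LOO model comparison (lower loo_ic is better)
#>   pga        elpd   -1383.54   loo_ic    2767.09
#>   naive      elpd    -165.93   loo_ic     331.86
#>   elpd difference (pga - naive): -1217.61 (SE 242.27)
#>   preferred: naive
```

Read the numbers the way a fisheries analyst would: under +4 °C the
thermal performance scalar collapses for most lakes — a mean 97.7%
decline in relative abundance, with 43 of 60 lakes (72%) crossing the
posterior extinction-probability threshold of 0.90, including 7 of the
24 lakes the species currently occupies. The naive quadratic model fits
the *current* data better (lower LOO-IC) — it is free to chase the
observed temperature gradient — but it can never predict extirpation:
its abundance stays positive even past $CT_{max}$. That contrast, fit
now versus physiological realism under extrapolation, is the package's
central point; `truncated_range_experiment()` stages it against a known
simulated truth.

For shell workflows, `inst/exec/pga` wraps the same functions as
subcommands (`simulate`, `fit`, `project`, `compare`, `diagnose`).

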