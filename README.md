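# bayeshaz

Bayesian testing of hazard-function equivalence for two-group
right-censored survival data, with power against **crossing hazards** —
the situation where the hazard ratio passes through 1 over time and the
classical log-rank test loses its signal through cancellation.

The package is aimed at biostatisticians comparing two arms of a survival
study (clinical trials, reliability data) who suspect the proportional
hazards assumption may fail, and at methodologists reproducing the
operating characteristics of rank tests under non-proportional
alternatives.

## The test

For data $D_{1:n} = \{(X_i, \delta_i, z_i)\}$ with observed time
$X_i = \min(T_i, C_i)$, event indicator $\delta_i$ and arm $z_i \in
\{0,1\}$, the time-varying-coefficient Cox model

$$\lambda(t \mid z) = \exp\{z\,\beta(t)\}\,\lambda_0(t)$$

reduces hazard equivalence to $M_0 : \beta(\cdot) \equiv 0$ versus
$M_1 : \beta(\cdot) \not\equiv 0$.  The log hazard ratio is expanded in a
B-spline basis gated by an inclusion indicator,
$\beta(t) = \eta \sum_{l=1}^{a_n} \gamma_l B_{d,a_n,l}(t)$, with a
spike-and-slab prior: $\eta \mid q \sim \text{Bernoulli}(q)$,
$q \sim \text{Unif}(0,1)$, and truncated-normal slabs
$\gamma_l \sim N(0, \sigma^2)I(|\gamma_l| < L)$.  Inference uses the Cox
**partial likelihood only** — the baseline hazard never needs a prior —
and a Metropolis-within-Gibbs sampler (compiled core) returns the
posterior inclusion probability $P(\eta = 1 \mid D_{1:n})$.  Equivalence
is rejected when it exceeds 0.5.  Because the decision is a model
choice, no weight function has to be picked in advance, which is exactly
what defeats the weighted log-rank family under an unanticipated
crossing.

Also included: the classical comparators (log-rank, Fleming–Harrington
weighted log-rank with pooled-KM weights $\hat S(t-)$ and $1-\hat S(t-)$,
Renyi supremum tests), a simulator for constant / step / crossing /
diverging hazard-ratio scenarios with censoring-rate-calibrated
truncated-exponential censoring, and a Monte-Carlo power-study driver.

## Worked example

Simulate a crossing-hazards trial (scenario M3: hazard ratio
$0.1 + 0.5t$, crossing 1 at $t = 1.8$, baseline rate 0.25, 30%
censoring) and test it:

```r
library(bayeshaz)

scn <- hazard_scenario("M3", censor_rate = 0.3)
ds  <- simulate_survival(scn, n = 100, seed = 1)
ds
#> Two-group right-censored survival dataset
#>   n = 100 (group 0: 50, group 1: 50), events = 75, tau = 6

fit <- bayes_hazard_test(ds, mcmc = mcmc_config(seed = 1))
fit
#> Bayesian test of hazard-function equivalence
#>   posterior P(eta = 1 | data) = 0.602  (raw mean of eta draws: 0.600)
#>   decision at threshold 0.50: reject equivalence of hazards
#>   basis: degree 2, 5 functions on [0.734, 5.15]; MH acceptance 0.26

log_rank_test(ds)$p.value
#> [1] 0.7240958
renyi_test(ds, "late")$p.value
#> [1] 0.1728772
```

The posterior puts 60% of its mass on a time-varying log hazard ratio,
so equivalence is rejected, while the log-rank p-value of 0.72 is blind
to the crossing (its early and late increments cancel) and even the
late-weighted Renyi test does not reach the 0.05 level here.

Power studies over a grid of scenarios:

```r
run_power_grid(hazard_scenario("M4"), sample_sizes = c(50, 100),
               censor_rates = c(0.3, 0.7), tests = c("proposed", "log_rank"),
               n_reps = 100, master_seed = 1)
```

A thin command-line front end over the same functions lives in
`inst/scripts/bayeshaz.R` (subcommands `simulate`, `test`, `power`).

To analyze the Gastrointestinal Tumor Study Group trial (a classic
crossing-hazards example), export the dataset from the CRAN package
`YPmodel` as a `time,event,group` CSV and run
`real_data_analysis("gi.csv")`; the function prints the export recipe if
the file is missing.

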