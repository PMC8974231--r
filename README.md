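# riskmove

Movement responses of a subordinate carnivore to competitor risk, from raw
GPS telemetry to a fitted mixed model — with a fully synthetic study
system for validation.

## The problem

Subordinate predators such as African wild dogs must hunt in landscapes
dominated by stronger competitors (lions) that steal kills and kill
adults and pups.  Because movement is among their most expensive
behaviours (an extra hour of movement costs a wild dog roughly half a
kilogram of food), *how* a subordinate adjusts movement to competitor
risk — slowing and lingering versus fleeing — shapes its energy budget
and ultimately its distribution.  The analysis this package implements
separates two responses:

* **proactive** — reduced movement in places the competitor uses heavily
  over the long term (a summed competitor utilization surface), and
* **reactive** — increased movement when a competitor is actually nearby
  (closest competitor fix within ±3 h and ≤ 2 km),

while controlling for prey-density proxies (vegetation class, distances
to rivers/tributaries), anthropogenic variables (protection designation,
distance to roads and the park boundary), season, and pack state
(breeding status, dependent pups).

## The method

1. **Motion variance (dBBMM).** Each group's GPS track is modelled with
   a dynamic Brownian bridge movement model: between consecutive fixes
   the animal follows a Brownian bridge with diffusion σ²ₘ estimated by a
   leave-one-out likelihood, and σ²ₘ varies along the track through
   windowed change-point segmentation (window 15 / margin 5 locations at
   twice-daily sampling ≙ one week / 48 h) with BIC model selection.
   σ²ₘ (m² per unit time) is the movement response: large when the
   animal displaces far, small when it lingers.
2. **Risk surface.** Competitor utilization distributions are rasterized
   per group and calendar interval (years and calendar halves), their
   95% isopleths merged into a study area, and their cell-wise sum forms
   the encounter-risk surface whose value (log-transformed) is extracted
   at every focal fix.
3. **Model.** The rounded motion variance is fit with a negative-binomial
   (NB2) mixed model, log link, a pack random intercept, and adaptive
   Gauss–Hermite quadrature (15 nodes), written in this package and
   cross-checked against glmmTMB; simulation-based goodness of fit
   compares NB against a gamma GLM.
4. **Synthetic truth.** Because the motivating field data are not
   public, a generator simulates the landscape, territorial
   Ornstein–Uhlenbeck competitor groups, and focal packs whose per-move
   displacement scale is `exp(b0 + β·covariates)` with known β — so the
   entire pipeline can be validated end to end, including sign recovery
   and type-I control under a null configuration.

## A worked example

```r
library(riskmove)

# the energetics of one extra hour of movement
movement_cost(mean_cost = 3.07, energy_density = 5.8, daily_intake = 2.5)
#> # A tibble: 1 × 2
#>   kg_per_hour pct_of_daily_intake
#>         <dbl>               <dbl>
#> 1        0.53                21.2

# full pipeline on a synthetic year: 3 competitor groups, 3 packs
cfg <- sim_config(seed = 3, n_prides = 3, n_packs = 3,
                  span = c("2018-01-01", "2018-12-31"))
rec <- end_to_end_recovery(cfg, dt = 900, quad_points = 8)
rec$report
#> # A tibble: 5 × 6
#>   term         estimate      z beta_true expected sign_match
#>   <chr>           <dbl>  <dbl>     <dbl>    <dbl> <lgl>
#> 1 log_lion_use  -0.0751  -3.80    -0.103   -0.206 TRUE
#> 2 near           0.0369   1.20     0.261    0.522 TRUE
#> 3 wet           -0.673  -25.1     -0.309   -0.618 TRUE
#> 4 pups          -0.722  -23.9     -0.355   -0.71  TRUE
#> 5 nonbreeding    2.40    53.1     1.03     2.05  TRUE
```

Reading the report: `beta_true` is the generative effect on the log
displacement scale; because motion variance scales with squared
displacement, the expected coefficient on the response scale is about
`2 * beta_true` (`expected`).  `estimate` is the fitted coefficient
(continuous terms rescaled back to per-unit), and `z` its Wald score.
Here all five signs are recovered; the short-lived "near" effect is
attenuated because windowed motion variance smooths per-move responses —
the report quantifies that attenuation instead of hiding it.

Useful entry points: `read_tracks()` / `split_bursts()` (telemetry IO),
`dynamic_variance()` (motion variance), `rasterize_ud()` /
`isopleth_cells()` / `build_risk_surface()` (space use),
`assemble_table()` (covariates), `fit_nb_glmm()` / `simulate_gof()`
(modelling), `run_pipeline()` (everything, with plain-text artifacts and
a hashed manifest), `autoplot()` / `plot_coefficients()` (figures).  The
methods vignette (`vignettes/movement-risk-methods.Rmd`) documents the
models, parameter choices and limitations.

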