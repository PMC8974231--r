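---
title: "Modelling a subordinate carnivore's movement response to competitor risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a subordinate carnivore's movement response to competitor risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`riskmove` implements a complete analysis pipeline for a question from
carnivore ecology: how does a subordinate predator (the motivating case is
the African wild dog) adjust its movement in response to a dominant
competitor (lions), relative to prey-density proxies, anthropogenic
features and its own group state?  Movement is measured as the *Brownian
motion variance* of a dynamic Brownian bridge movement model (dBBMM)
fitted to GPS telemetry: a per-fix diffusion parameter, in m² per unit
time, that is large when the animal displaces far per unit time and small
when it lingers.  The analysis distinguishes

* a **proactive** response: avoidance of places lions use intensively in
  the long term, measured by a summed lion utilization surface, and
* a **reactive** response: flight when a lion is actually nearby,
  measured by a near/far classification of each fix against the closest
  lion fix in a time window.

This vignette documents the models, the estimation choices, the tunable
parameters, what the synthetic-data generator does and does not emulate,
and the package's known limitations.

## The dynamic bridge motion-variance model

For consecutive fixes $z_{i-1}, z_{i+1}$ at times $t_{i-1}, t_{i+1}$, the
position of the animal at an intermediate time is modelled as a Brownian
bridge: isotropic bivariate normal with mean on the chord and per-coordinate
variance

$$\operatorname{Var}(t) \;=\; T\,\alpha(1-\alpha)\,\sigma^2_m \;+\;
(1-\alpha)^2\delta^2 + \alpha^2\delta^2,$$

where $\alpha = (t - t_{i-1})/T$, $T = t_{i+1} - t_{i-1}$, $\sigma^2_m$ is
the Brownian motion variance and $\delta$ the GPS location error SD
(default 1 m; at this sampling scale animal displacements are hundreds to
thousands of meters, so the error term is minor).

$\sigma^2_m$ is estimated by a leave-one-out likelihood
(`static_sigma2_mle()`): fixes at even positions anchor bridges, the
intermediate (odd-position) fixes are scored under the bridge density, and
the product of those densities is maximized over $\sigma^2_m$.  The
maximizer is an iteratively zoomed grid search on $\log \sigma^2$ (17
points, 5 zoom levels, bounds $10^{-10}$–$10^{7}$ m² s⁻¹, ties toward the
smaller value): monotone transformations of the bounds make the search
scale-free, the final resolution (≈0.1% in $\sigma^2$) is far below the
statistical uncertainty of the estimate, and the same code path serves both
the static and the windowed fits so degenerate configurations agree
exactly.  Tests verify the maximizer against an independently coded dense
grid oracle.

### Change-point segmentation

`dynamic_variance()` lets $\sigma^2_m$ vary along the track: a window of
`window` fixes slides one fix at a time, and within every window a
no-break model (one variance) competes against one-break models with the
breakpoint at every fix that retains at least `margin` fixes on each side.
All candidates are scored **on the same leave-one-out terms** — a break
only partitions the window's terms between two separately estimated
variances — so the likelihoods are nested and comparable, and model
selection uses BIC with $k = 1$ or $2$ variance parameters and the number
of leave-one-out terms as the sample size.  (An earlier design that
re-derived the term set per segment allowed a break model to *drop* a
term and win spuriously; the fixed-term formulation removes that
artifact.)  Each fix's final $\sigma^2_m$ is the unweighted mean of the
assignments from every window covering it, margin positions included; the
first and last fix of a burst are covered by exactly one window.

Window and margin are specified in *locations* and derive from
biologically motivated durations by fence-post counting
(`duration_to_locations()`): a 48-h margin and one-week window at
twice-daily fixes give 5 and 15 locations.  The package deliberately
exposes the counts directly rather than the durations, because published
counts for other sampling regimes do not always follow a single
conversion rule.

Tracks are split into bursts wherever consecutive fixes are more than
`max_gap = 36` h apart (three missed twice-daily fixes) and bridges are
never computed across burst boundaries: bridging a multi-day collar gap
produces a meaningless low-variance corridor.

Units: $\sigma^2_m$ is reported in m² per `time_unit` (seconds by
default; the pipeline uses hours so that the rounded integer response is
large and rounding is immaterial).  Correctness is unit-covariant and
tested as such.

## Utilization distributions, isopleths and the risk surface

`rasterize_ud()` integrates the bridge density of every segment over a
square grid (default cell 500 m), evaluating the bridge at uniformly
spaced times (default `dt` 300 s in standalone use; 900 s in the
pipeline), weighting by the time step, integrating each Gaussian exactly
over cells with normal-CDF differences, and normalizing the raster to
total mass 1.  The per-segment diffusion is the mean of the two endpoint
motion variances — the least-structured reconciliation of a per-fix
series to per-segment diffusion.  A grid that truncates ≥0.1% of the
bridge mass is rejected with the required extent in the error.

`isopleth_cells()` returns the smallest set of highest-density cells
reaching the target coverage (default 95%).  Exact value ties beyond the
required mass are resolved in cell order, keeping the set minimal and
deterministic — so a uniform distribution over 100 cells yields exactly
95 cells at the 95% level.  Isopleth "polygons" are unions of grid cells,
not smoothed contours: inclusion tests then agree exactly with the
probability accounting, at the cost of blocky boundaries.

The **study area** is the union of all competitor-group isopleths
(merged where they overlap), optionally extended by *exception zones* —
well-monitored polygons known to hold no resident competitor groups.
Focal fixes are retained iff inside the study area or an exception zone;
inclusion is boundary-closed (a fix exactly on a cell edge belongs to the
area if either adjacent cell does).  The **risk surface** for an
aggregation interval is the cell-wise sum of the per-group utilization
rasters on the shared grid; each group's raster is normalized to 1 before
summation regardless of monitoring span (the unweighted reading; a
monitored-days weighting would be a one-line change where unequal spans
matter).  Risk values are extracted at fixes by cell lookup with
half-open ownership, no interpolation.

Aggregation intervals are whole calendar years or calendar halves
(Jan 1–Jun 30, Jul 1–Dec 31): this calendar alignment is the only one that
reproduces the deployment arithmetic of a mid-2017 through 2020 study
(seven semiannual, three annual layers).

## The covariate table

One row per included focal fix (`assemble_table()`):

| covariate | definition | default |
|---|---|---|
| `response` | $\sigma^2_m$ rounded half away from zero | — |
| `lion_use`, `log_lion_use` | risk-surface value at the fix; natural log | error on ≤ 0 unless `epsilon` set |
| `proximity` | near iff a competitor fix within 2000 m (inclusive) and ±3 h | `far` reference; empty window → far, flagged |
| `season` | wet Dec 1–May 1 inclusive (year-wrapping), else dry | `dry` reference |
| `pups` | presence ranges (den emergence → Dec 31) | `absent` reference |
| `breeding` | breeding/non-breeding status ranges | `breeding` reference |
| `landuse` | park polygon / management-area ring / unprotected | `GMA` reference |
| `vegetation` | integer-coded raster class | `closed` reference |
| `dist_*` | Euclidean distance to tributaries, river, park boundary, roads (m) | — |

The "6-h window" for proximity is read as total width 6 h (±3 h), the
conservative interpretation that guarantees at least one competitor fix
per collared group at 4-h sampling; both half-width and threshold are
arguments.  All continuous predictors get centred/scaled copies (`*_s`),
computed on the assembled (per-timescale) table; a constant predictor is
centred to zero rather than divided by a zero SD.  Collinearity is
checked with generalized variance inflation factors computed from
correlation-matrix determinants (`gvif()`), valid for multi-column
categorical terms and verified against `car::vif`.

## The negative-binomial mixed model

The response is overdispersed count-like data spanning zero to the
hundreds of thousands, modelled as NB2 ("quadratic" parameterization,
variance $\mu + \mu^2/\theta$) with a log link, the fixed effects above,
and a group (pack) random intercept:

$$y_{ij} \mid u_j \sim \mathrm{NB2}\!\left(\mu_{ij} = e^{x_{ij}^\top b + u_j},\, \theta\right),
\qquad u_j \sim N(0, \sigma^2_{\text{pack}}).$$

`fit_nb_glmm()` maximizes the marginal likelihood with **adaptive
Gauss–Hermite quadrature** (default 15 nodes): at every likelihood
evaluation the integrand's mode and curvature are found per group by
damped Newton iteration (vectorized across groups), and the Hermite nodes
are centred and scaled there.  $\theta$ and $\sigma_{\text{pack}}$ are
optimized on the log scale; boundary fits
($\sigma^2_{\text{pack}} \approx 0$) are reported, not suppressed, and a
single-group dataset degenerates (with a warning) to the fixed-effects
fit with the variance pinned at zero.  Standard errors come from the
inverse observed information (numerical Hessian), with Wald $z$ and
two-sided normal $p$.  Starting values are the fixed-effects-only
`MASS::glm.nb` fit with $\sigma^2_{\text{pack}} = 0.1$.  The tests verify
the fitter against closed forms (intercept-only), self-simulation
recovery, the $\sigma^2 \to 0$ boundary (agreement with the plain NB GLM
likelihood to $10^{-4}$), quadrature-refinement stability, and an
independent mixed-model implementation (glmmTMB) — the latter is used
only as a cross-check, never as the estimator.

Comparison fits: `fit_nb_glm()` (no random effect; AIC comparison
verifies that the intercept is supported when group effects exist) and
`fit_gamma_glm()` (gamma GLM with log link on the un-rounded response,
used only for the goodness-of-fit contrast).  `simulate_gof()` draws
response vectors from a fitted model — redrawing random intercepts each
time — and compares simulated with observed distributions within subsets
defined by categorical predictors; its summary statistic is a
size-weighted mean Kolmogorov–Smirnov distance, and on NB-generated data
the NB model beats the gamma on this statistic.

A caveat carried over from the study design: consecutive fixes of a pack
are serially dependent, and the window-averaged motion variance is
strongly autocorrelated by construction.  The model (like the original
analysis) does not correct for this, so Wald $z$ values are somewhat
anti-conservative; the type-I simulation below quantifies the effect
rather than hiding it.

## The synthetic study system

Because the motivating field data are not public, `sim_config()` +
`simulate_study()` generate a study system with known ground truth:

* **Landscape** — a square of 60 km: a central park polygon inside a
  management-area ring (unprotected outside), a meandering main river,
  three tributaries, two roads, and a three-class vegetation raster cut
  from a smooth random field.
* **Competitor groups ("prides")** — Ornstein–Uhlenbeck walks around
  territory centres spread through the park, sampled every 4 h, using the
  exact OU transition (attraction 0.02 h⁻¹, step SD 1000 m ⇒ stationary
  SD ≈ 2.6 km, a realistic territory scale).  The analytic stationary
  density is recorded as ground truth.
* **Focal groups ("packs")** — twice-daily fixes at 08:00 and 18:30.
  Each move's expected displacement scale is
  $\exp(b_{0,\text{pack}} + \beta_{\text{lu}}\,x_{\text{lu}} +
  \beta_{\text{near}}\,\mathbb 1[\text{near}] + \beta_{\text{wet}}\,\mathbb 1[\text{wet}]
  + \beta_{\text{pups}}\,\mathbb 1[\text{pups}] + \beta_{\text{nb}}\,\mathbb 1[\text{non-breeding}])$,
  with $x_{\text{lu}}$ the log of the *analytic* pride stationary density
  and "near" determined endogenously from the realized lion tracks (2 km,
  ±3 h) — deliberately mirroring the proactive-risk construct (the animal
  responds to long-term use; the pipeline estimates it from realized
  tracks).  Default effect sizes take the signs and magnitudes of the
  published wild-dog coefficients (−0.103, +0.261, −0.309, −0.355,
  +1.027).  The last pack is a newly formed non-breeding group for the
  first half of the span and then establishes and breeds — without that
  transition the breeding effect is aliased with pack identity.
* Three generator choices matter for fidelity of the ground truth.
  (1) The log-density covariate is floored at the single-pride density
  3.5 stationary SDs out: perceived risk saturates far from any
  territory instead of diverging to −∞ (which would make step scales
  explode).  (2) The home-range tendency of packs biases each step's *direction*
  toward the home centre (blend weight 0.7, ramping up over 5 km) while
  the step's *magnitude* remains exactly the risk-dependent scale times a
  bivariate-normal draw.  A positional drift (e.g. an OU pull) would make
  displacement depend on where the pack is, which both breaks the
  generative identity (mean log displacement must shift by exactly
  $\beta$) and manufactures spurious correlation between displacement and
  lion density under a null configuration; direction bias keeps the
  magnitude distribution position-free by construction.  (3) Pack intercepts vary
  (SD 0.3), so marginal near/far contrasts are confounded between packs
  by design — tests of the pure generative identity silence them, while
  the mixed model handles them through the random intercept.

What the generator does **not** emulate: behaviourally detailed hunting
or denning, fix failures and irregular sampling, GPS outliers, seasonal
territory shifts of the competitor, and landscape-dependent movement
(rivers and roads influence the covariate table, not the simulated
trajectories).  Passing tests therefore demonstrate the pipeline's
statistical correctness under a faithful generative model, not the
ecological fidelity of any coefficient to a real system.

Because the response is proportional to the *squared* displacement scale,
a generative effect $\beta$ appears on the response log scale as
approximately $2\beta$; `end_to_end_recovery()` reports estimates next to
both the generative and the doubled value, and quantifies the attenuation
that remains because windowed motion variance is a smoothed proxy for
per-move displacement (short-lived effects such as "near" attenuate most).

## Problem sizes and reproducibility

The validation harness runs the full pipeline — simulation, dBBMM for
both species, utilization rasters, study area, risk surface, covariates,
mixed model — on one-year spans with 3 prides and 3 packs (about 2,200
focal fixes and 6,500 competitor fixes per replicate), 20 replicates with
the published effect signs and 20 with all effects zero; these sizes give
stable sign-recovery and type-I summaries while keeping a full run in the
tens of seconds.  Every stochastic step is seeded; identical
configurations reproduce byte-identical tracks, layers and schedules.
`scripts/acceptance.R --seed <s> --out <path>` recomputes all headline
quantities from scratch.

```{r example}
library(riskmove)

cfg <- sim_config(seed = 1, n_prides = 3, n_packs = 3,
                  span = c("2018-01-01", "2018-12-31"))
rec <- end_to_end_recovery(cfg, dt = 900, quad_points = 8)
rec$report                    # true vs estimated effects
coefficient_table(rec$pipeline$fit)
autoplot(rec$pipeline$risk_surfaces[[1]])
```

## Known limitations

* Wald inference ignores residual temporal autocorrelation (see above);
  lag-aware standard errors are future work.
* Isopleth boundaries are rasterized cell unions; published workflows
  that smooth polygons in a GIS will disagree slightly near edges.
* The breakpoint search allows one break per window; multiple breaks
  emerge only through window overlap, as in the canonical formulation.
* The gamma comparison fit exists for the goodness-of-fit contrast only;
  its shape estimate falls back to a deviance-based value when the ML
  iteration degenerates.
* Real collar data arrive in vendor formats with fix-quality flags; the
  package reads only the plain CSV schema documented in `read_tracks()`.
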