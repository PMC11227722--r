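# habsel — behavior-stratified habitat selection from GPS tracks

habsel is an R package for wildlife ecologists analysing GPS-collar data
from forest animals: it asks whether an animal selects different habitat
while **moving** than while **resting**, how selection responds to past
forest management (openings, edges, patch structure), and whether selection
changes with availability (a *functional response* — the specialist vs.
generalist question). The motivating system is a small forest carnivore in
managed montane conifer forest, collared with accelerometer-informed GPS
schedules; everything is parameterised, so any two-state use–availability
study fits.

## What it computes

- **Behavior classification and thinning** — accelerometer thresholds
  (resting < 6400, fast > 48,000) or fix-interval rules (120 ± 5 min rest,
  20-min movement), greedy thinning of 5-min bursts to 20-min series, and a
  mixed-logistic screen for habitat-biased GPS fix failure.
- **Home ranges and availability** — 100% minimum convex polygons, 5-km
  outward buffers, uniform availability samples at 1:20 used:available from
  one shared per-individual pool.
- **Landscape covariates on a 10-m grid** — exact circular-window means at
  100/400/4000 m, topographic position index, slope and linearized aspect,
  and a forest-opening patch layer: quartile canopy classes (≤25 / 26–50 /
  51–75 / >75%), two-pass 3×3 modal smoothing, rook-connected patches with
  a strict 0.4-ha minimum, patch size, distance to edge, and edge density
  (km/km²).
- **Resource selection functions** — binomial GLMMs with an individual
  random intercept (glmmTMB),

  `logit P(used) = β₀ + bᵢ + βᵀx`,

  with z-scored covariates, a strict |r| > 0.6 collinearity screen,
  univariate AICc scale selection, hypothesis-set competition by
  AICc = −2ℓ + 2K + 2K(K+1)/(n−K−1), and behavior × covariate interaction
  models (dense canopy and moving as reference levels).
- **Functional responses** — per-individual log mean use regressed on log
  mean availability (OLS, 90% t-intervals); slope CI below 1 ⇒
  `decreasing_FR` (use stays high where availability is low), slope 1 with
  intercept 0 ⇒ `proportional`.
- **A synthetic world with known truth** — Gaussian-random-field landscapes
  and a two-state movement simulator whose long-run utilization is exactly
  the target selection surface (local Gibbs kernel), so every estimator in
  the chain is validated against known coefficients.

## Worked example

A six-animal synthetic scenario, simulated and analysed end to end:

```r
library(habsel)

cfg <- run_config(
  seed = 42,
  landscape  = list(extent = c(1500, 1200), resolution = 10,
                    autocorrelation_range = 150,
                    class_mixture = c(0.5, 0.3, 0.2),
                    canopy_beta = c(2, 1.2), canopy_gradient = 0),
  population = list(n_individuals = 6, n_fixes = 150,
                    availability_gradient = "none", margin = 80),
  truth = list(beta_moving = c(canopy = 0.04),
               beta_resting = c(canopy = 0.08),
               switch_prob = c(0.10, 0.30),
               relocation_radius = c(moving = 2500, resting = 2500)),
  availability = list(ratio = 10, buffer = 300),
  scales = c(100, 400),
  hypotheses = list(canopy = "canopy", abiotic = c("elev", "slope"),
                    openings = c("edge_density", "patch_size_ha")),
  fr_covariates = "canopy"
)
res <- run_pipeline(cfg, out_dir = "demo_run")
#> [habsel] simulated 900 fixes for 6 individuals
#> [habsel] 639 moving and 261 resting used points
#> [habsel] 23 patches retained
#> [habsel] moving: top model canopy (w = 1)
#> [habsel] resting: top model canopy (w = 1)

res$rsf$moving$selection
#>      model                       covariates K    AICc delta_AICc weight       LL
#> 1   canopy                       canopy_100 3 4140.87      0.000  1.000 -2067.44
#> 2 openings edge_density_100 + patch_size_ha 4 4244.79    103.919  ~0    -2118.39
#> 3  abiotic                     elev + slope 4 4257.18    116.311  ~0    -2124.59
#> 4     null                                  2 4286.58    145.702  ~0    -2141.29

tidy(res$rsf$moving$fits$canopy)
#>          term estimate std_error conf_low conf_high
#> 1 (Intercept)   -2.419    0.0514   -2.519     -2.32
#> 2  canopy_100    0.552    0.0501    0.453      0.65
```

The data were simulated with positive canopy selection, and the canopy
hypothesis wins the AICc competition outright (Akaike weight 1); the
standardized coefficient 0.55 means the odds of use rise by e^0.55 ≈ 1.7
per standard deviation of 100-m canopy cover.

Functional responses need an availability gradient across individuals. On
the bundled specialist scenario (resting animals strongly prefer dense
canopy; home ranges differ in how much of it they contain):

```r
w  <- validation_landscape("specialist")
d  <- validation_designs(w, validation_truth("specialist"), seed = 7,
                         placement = "strips")
functional_response_suite(d$design_moving, d$design_resting, "canopy_100")
#>    covariate behavior  n slope slope_lo slope_hi intercept         label
#> 1 canopy_100   moving 12 1.107   0.9399    1.275    -0.453  proportional
#> 2 canopy_100  resting 12 0.104  -0.0605    0.269     4.015 decreasing_FR
```

Moving use tracks availability (slope ≈ 1: generalist), while resting use
is flat across the availability gradient (slope ≈ 0.1, 90% CI below 1):
resting animals keep using dense canopy at high rates even where it is
scarce — the specialist signature. `autoplot()` on the result draws the
mean-use vs. mean-availability panels with the 1:1 reference line.

A thin CLI over the same functions ships in `inst/cli/habsel.R`
(`run`, `simulate`, `validate` subcommands).

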