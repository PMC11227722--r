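---
title: "Behavior-stratified habitat selection: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavior-stratified habitat selection: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habsel)
```

## The analysis habsel implements

habsel is built around third-order resource selection: given GPS fixes from
collared animals (the *used* points) and random points drawn from each
animal's home range (the *available* points), a binomial GLMM

$$\operatorname{logit} P(\text{used}) = \beta_0 + b_i + \boldsymbol\beta^\top
\mathbf{x}, \qquad b_i \sim N(0, \sigma^2_{id})$$

estimates selection coefficients $\boldsymbol\beta$ whose exponential is
proportional to the relative probability of use (an exponential RSF). The
package stratifies this analysis by behavioral state — fast, regular fixes
while an animal moves versus sparse fixes while it rests — because a
forest carnivore may tolerate open, fragmented stands while commuting yet
require dense canopy to rest. Three questions structure the workflow:

1. **Do moving and resting animals select different forest features?**
   Separate RSFs per behavior, with a candidate set of hypothesis models
   (terrain, canopy, forest openings, composition, ...) compared by AICc.
2. **How does past forest management interact with behavior?** Combined
   designs with state-interaction models on the patch covariates (canopy
   category, patch edge density, patch size, distance to edge), dense canopy
   and the moving state as reference levels.
3. **Is selection availability-dependent?** Per-covariate functional
   responses: ordinary least squares of log mean use on log mean
   availability across individuals, 90% confidence intervals, and a
   proportional / decreasing / increasing classification.

## Preprocessing rules and their constants

* **Behavior from accelerometers.** Fixes with on-board activity below
  6400 (unitless tri-axial summary) are resting; everything above — the
  moderate band and fast movement above 48,000 — is pooled as moving,
  because collars sample the intermediate and fast bands at 20- and 5-min
  schedules that together form the movement dataset. Without activity
  values, the fix interval decides: 120 ± 5 min is resting, 5- or 20-min
  (± 2) is moving, anything else is unknown.
* **Thinning.** 5-min bursts are thinned to a uniform 20-min movement
  series by a greedy forward pass (keep the earliest fix at least
  `target − tolerance` after the last kept fix). The pass is idempotent and
  simply resumes after gaps; the ± 2 min tolerance is configurable.
* **Home ranges.** 100% minimum convex polygons, buffered 5 km outward
  (about one day's travel) for availability sampling; both behavior designs
  draw from one shared uniform pool per individual at 1:20 used:available,
  the smaller design's pool nested in the larger's.
* **Fix-success screening.** A mixed logistic model of fix success on
  environmental covariates (random intercept per animal) flags
  habitat-driven fix loss, which would bias selection estimates; the check
  is a simplified logistic screen, not a full detection model.

## Landscape covariates

All covariates live on a 10-m planar grid held in a lightweight matrix
raster (`hs_raster`); no geographic CRS handling is attempted. Circular
neighborhood means at 100 m, 400 m and 4000 m (scales matched to 10-min,
hourly and daily movement distances) are computed by an exact run-length /
prefix-sum decomposition of the circular window, so they agree with
brute-force recomputation to machine precision — that exactness is tested,
not assumed. Terrain gives slope (Horn's 3×3 differences), a topographic
position index (cell elevation minus the window mean, center excluded;
disc neighborhoods, since an annulus was an equally defensible choice), and
a linearized aspect: the fold transform $(1 - \cos(\text{aspect} -
30^\circ))/2$, 0 at the coolest azimuth and 1 opposite it, with flat cells
at 0.5.

The forest-opening patch layer starts from quartile canopy classes (≤ 25,
26–50, 51–75, > 75%), smoothed by two passes of a 3×3 modal filter. The
"30 m neighborhood" is interpreted as a 30 m × 30 m window (3×3 cells at
10 m): a literal 30 m² window would be smaller than one cell. Ties keep the
center cell, which makes the filter deterministic and minimally invasive.
Connected components use rook (4-)adjacency so single-pixel diagonal
threads cannot stitch patches together. Components under 0.4 ha — the rule
is a strict less-than, so a 0.40-ha patch survives — are absorbed into the
neighbor sharing the longest boundary (ties toward the lower canopy class),
rather than left as holes, so every location receives a patch category.
Edge density converts patch boundaries to lines (the extent border is
excluded as a map artifact, not a stand edge), attributes half of each
shared cell edge to the cell on either side, and divides the circular
window's summed length by the window area (km/km²). Distance to edge is the
exact Euclidean distance to the nearest boundary segment.

## The RSF machinery

Covariates are z-scored per design — the conventional $(x - \mu)/\sigma$ —
with the scaling recorded so coefficients and intervals can be reported on
the raw scale. Pairs with $|r| > 0.6$ (strictly) may not share a model; the
univariate scale competition picks each covariate's most predictive scale
by AICc with ties to the smallest scale. Model competition uses
$\mathrm{AICc} = -2\ell + 2K + 2K(K+1)/(n-K-1)$ with $n$ the design's row
count and $K$ counting fixed effects, intercept and the random-intercept
variance. GLMMs are fitted by glmmTMB (Laplace approximation); a fit with a
single individual collapses to plain logistic regression, which the tests
verify against `glm()` and against the closed-form 2×2 log odds ratio.
Near-empty category-state cells in the interaction models (one resting
point in sparse canopy is a realistic outcome) produce wide Wald intervals
with a warning rather than an error, since that is information, not a
failure.

## Functional responses

For each covariate and behavior, individuals are the data points: the mean
of the covariate over an individual's used points regressed (log–log,
ordinary least squares, t-intervals with $n-2$ df) on its mean over the
availability pool. Slope 1 with intercept 0 is proportional use; a slope
CI entirely below 1 is a decreasing functional response — high use
maintained where availability is low, the specialist signature; entirely
above 1, increasing; anything else indeterminate, all at 90% confidence.
Covariates with non-positive means (TPI is signed) are shifted by the
global minimum minus a small epsilon before logging; the offset is recorded
in the result. Individuals with fewer than 5 used points for a covariate
are excluded — with very rare categories there is simply nothing to
regress. A caveat worth knowing: the OLS intervals assume roughly equal
log-scale noise across individuals. When per-individual sample sizes or
relative covariate spreads differ wildly, the intervals run anti-
conservative, which is a property of the published method itself, not of
this implementation.

## The simulator and what it does (not) emulate

`generate_landscape()` builds Gaussian-random-field canopy, elevation and
clumped vegetation classes by smoothing white noise with a Gaussian kernel
(`autocorrelation_range` equal to the resolution degenerates to white
noise, which the tests verify via Moran's I). Canopy ranks pass through a
Beta quantile; the default `c(5.4, 1)` reproduces a dense-dominated montane
landscape with ~79% of cells above 75% cover. Two gradient mechanisms
support functional-response designs: a rank-blend gradient (the whole
canopy distribution shifts west to east; with `canopy_scale = "log"` the
relative spread stays constant, the regime in which log–log FR errors are
homoscedastic) and a shape gradient (`canopy_shape_gradient`), under which
every home range spans the full canopy range but ranges differ in how much
dense cover they hold — the contrast that lets a fixed dense-canopy
preference appear as a decreasing functional response.

Movement is a two-state Markov chain (20-min moving fixes, 120-min resting
fixes; activity values drawn on the correct side of the thresholds). The
default movement kernel is a local Gibbs sampler: draw an intermediate disc
center uniformly within the state's relocation radius, then relocate to a
cell chosen with probability proportional to $\exp(\boldsymbol\beta^\top
\mathbf{x})$ within the disc. Its long-run utilization is exactly the
target selection surface, which is what makes parameter-recovery validation
meaningful. The classical step-selection simulator (gamma step lengths,
uniform turns, best of K = 50 candidates) is kept as `kernel = "gamma_ssf"`
for movement realism, but its equilibrium roughly squares the selection
weights on smooth fields, so it is deliberately not the validation default.
The moving step scale is calibrated to an hourly movement distance of about
370 m (three 20-min steps of ~123 m). The simulator does not attempt
energetics, den-site mechanics, temporal autocorrelation in behavior beyond
the Markov chain, or GPS positional error.

## Validation scenarios and problem sizes

The `validate_*()` functions re-simulate the whole chain at the study's
design ratios — 12 individuals, 1:20 availability, resting a minority
state — on landscapes 2–3 km across at 10 m, sizes chosen so a replicate
runs in seconds while windows at the 100-m and 400-m scales stay
meaningful (a 4-km window would exceed these landscapes; on real data the
4000-m scale is computed the same way).

Two placement regimes matter. *Shared* placement overlaps all home ranges
on one area, giving every individual the same availability distribution;
this is the regime for coefficient recovery, because with the used:available
ratio fixed by design the individual intercepts carry no information, and
between-individual availability contrasts would otherwise attenuate the
pooled slope — a genuine property of use-availability GLMMs, worth knowing
when interpreting field estimates. *Strip* placement gives each individual
its own segment of a west-east gradient, the precondition for functional
responses. Recovery uses equilibrium sampling (relocation radius beyond the
home-range diameter), so fixes are independent draws from the state's
selection surface and the fitted model is correctly specified; 95% CI
coverage and AICc competition are then meaningful quantities. Coverage is
reported over 50 replicates, functional-response labels over 50
(specialist) and 100 (proportional) replicates, and the interaction sign
pattern over 50; the type-I calibration of the FR classifier itself is also
property-tested directly on means drawn from the proportional model.

## Known limitations

* Planar metric coordinates only; bring your own projection.
* The availability polygon is convex (MCP-based); concave home ranges are
  out of scope.
* The logistic RSF is the unweighted use-availability approximation of the
  underlying point process, matching standard practice, not an
  infinitely-weighted or point-process likelihood.
* The fix-bias screen is a logistic regression on attempt covariates, not a
  full state-space detection model.
* Patch absorption of sub-minimum components merges them into neighbors;
  whether an original field workflow would instead leave holes is
  unknowable from a published description, and the choice is documented
  rather than configurable.
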