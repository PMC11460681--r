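---
title: "Methods: comparing mechanistic and field-derived mosquito thermal responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing mechanistic and field-derived mosquito thermal responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoniche)
```

## The scientific problem

Mosquito vectors are small-bodied ectotherms whose life-history traits
(development rate, fecundity, egg-to-adult survival, adult mortality)
respond unimodally to temperature, with lower thermal limits, intermediate
optima, and upper limits measured in laboratory experiments. Composing those
trait curves yields a mechanistic, temperature-dependent equilibrium
abundance,

$$M(T) = \frac{\mathrm{EFD}(T)\,\mathrm{pEA}(T)\,\mathrm{MDR}(T)}{\mu(T)^2},$$

whose critical temperatures summarize how a species *should* respond to
temperature. Whether wild populations actually respect those laboratory
limits is a separate, empirical question: occurrence records plus
environmental covariates can be fed into a species distribution model
(SDM), and the model's fitted temperature response — a univariate partial
dependence curve of occurrence probability — yields *field-derived* thermal
minima and optima to compare against the mechanistic ones.

This package implements that comparison pipeline end to end, together with
a synthetic-world generator with a *known* thermal truth so that every
stage can be validated by parameter recovery, entirely offline.

## The synthetic world and its ground truth

`generate_world()` builds a regular lon/lat grid (default 60 × 60 cells of
0.05°) carrying a temperature-mean field (a smooth south-to-north gradient
spanning from 7 °C above the true upper limit down to 7 °C below the true
lower limit, plus smooth noise), a temperature-SD field, five auxiliary
covariates (vegetation index, dry-quarter precipitation, human density,
wind speed, relative humidity), and a land mask. The auxiliary covariates
are constructed as mixtures of the standardized temperature field and
independent smooth noise with mixing weights of at most 0.48, so the
covariate stack passes the |r| < 0.8 collinearity screen by construction
while remaining realistically temperature-correlated.

The true occurrence-probability response is a generalized Briere curve,

$$s(T) \propto T\,(T - T_\min)\,(T_\max - T)^b,$$

zero outside $(T_\min, T_\max)$. A plain Briere-1 curve's optimum is fixed
by its two zeroes, so the right-tail exponent $b$ is solved in closed form
from the critical-point condition at $T_{opt}$, placing the maximum exactly
at the requested optimum. The reference truth is
$T_\min^* = 12$, $T_{opt}^* = 27$, $T_\max^* = 36$ °C with peak occurrence
probability 0.9 — values in the range reported for warm-climate vector
species.

Occurrence records are drawn with replacement with probability proportional
to suitability × sampling effort (a clustered "bias" surface,
$w \propto e^{\kappa z}$ for a smooth standardized field $z$ and
concentration $\kappa = 1$), then jittered within their cell and decorated
with reporting metadata. A fixed 5% of records carries a labeled violation
of the cleaning rules (excess coordinate uncertainty, one-decimal
coordinates, fossil or unknown basis of record, out-of-period date), so the
filter's expected survivor counts are known exactly. Ecoregions are a
discrete Voronoi tessellation of the grid; all distances use an
equirectangular approximation in km, adequate at desk-scale extents.

What the generator deliberately does *not* emulate: real GBIF taxonomy,
spatially autocorrelated detection error, coastline geometry, or
disequilibrium range dynamics (invasion fronts). Passing recovery tests
therefore demonstrates that the *pipeline machinery* is unbiased under its
own assumptions — not that real-data inferences are unbiased.

## Activity seasons

Temperature predictors can be restricted to the season a species is
actually active:

- **Photoperiod rule** — a day is in season iff day length ≥ 9 h
  (inclusive). Day length comes from the closed-form CBM model (Forsythe et
  al. 1995) with daylight defined sunrise-to-sunset at solar center
  (twilight coefficient 0); the model is configurable should a
  twilight-inclusive definition be wanted. Hemisphere symmetry holds to
  about 0.2 h up to ±40° latitude and degrades slowly poleward (orbital
  eccentricity), which is inherent to any calendar-accurate formula.
- **Precipitation rule** — a day is in season iff the trailing 30-day
  precipitation total is ≥ 50 mm (inclusive), computed on a cyclic 365-day
  climatological year so the window wraps the year boundary.
- **Year-round** — no mask.

In-season statistics use the population (divisor *n*) standard deviation:
the mask defines the complete population of in-season days rather than a
sample from it. A `sd_type = "sample"` switch is provided. In-season
statistics pool all in-season days rather than averaging per-year
statistics; with a climatological average year the two coincide.

## Occurrence cleaning and thinning

`filter_records()` applies, in a fixed order: malformed coordinates; study
period (2000–2019 by default); fossil/unknown basis of record; coordinate
uncertainty < 1000 m *or* missing uncertainty with both coordinates
reported to ≥ 2 decimal places; land; covariate completeness; and positive
activity-season length (skipped for year-round species). Decimal precision
travels as explicit metadata (`coord_decimals`) because trailing zeros
cannot be recovered from parsed floats. The per-rule rejection tally
depends on rule order (first failing rule is charged); the survivor set
does not. Survivors are thinned to unique cell centroids — one presence per
occupied cell — which both deduplicates and blunts sampling bias.

## Background sampling

The accessible area is the union of ecoregions intersecting any occurrence
centroid buffered by 200 km (an upper bound on wind-assisted dispersal)
plus all rook-adjacent ecoregions; rook rather than point-touch adjacency
because corner contacts are degenerate for Voronoi tessellations. Effort
tallies are restricted to the area's land cells and renormalized (only
relative weights matter for sampling); if every eligible cell has zero
effort the mask falls back to uniform. Exactly twice as many background
centroids as presence centroids are drawn without replacement, excluding
presence cells — a cell cannot be both presence and pseudo-absence in one
training table. Sampling uses Efraimidis–Spirakis exponential keys, which
is distributionally identical to sequential draw-and-renormalize; tests
verify inclusion frequencies against the exact sequential law. A
thermal-breadth check warns (never fails) when the background temperature
range does not cover the occurrence range on both tails.

## Model fitting

Gradient-boosted classification trees (xgboost, histogram method, single
thread for reproducibility) discriminate presence from background cells.
Six hyperparameters are tuned — learning rate [1e-4, 0.3], maximum depth
[2, 50], minimum child weight [1, 50], row subsample [0.25, 1], column
subsample [0.5, 1], minimum split loss [0, 100] — by Bayesian optimization:
a Latin-hypercube initial design followed by Gaussian-process /
expected-improvement proposals, each evaluated by stratified 5-fold
cross-validated log loss with early-stopped selection of the boosting-round
count, and the argmin proposal retained. Folds are stratified to avoid
single-class folds at small *n*. Early-stopping patience defaults to 50
stagnant rounds (25 in the desk profile); both are configurable. Class
imbalance is by design 2:1 and left unreweighted.

Two presets exist: `profile_paper()` (20 bootstrap iterations, ≤ 24
optimization rounds, ≤ 10,000 boosting rounds) mirrors the published
budgets; `profile_desk()` (5 iterations, 8 rounds, ≤ 300 boosting rounds,
64 histogram bins) is the package's own reference scale for simulation and
testing — chosen so a full five-seed recovery study runs in about a minute
on one CPU while leaving the recovery signal intact. The vignette's and
test suite's problem sizes (60 × 60 world, 1,000 records, 5 iterations)
are this preset's study conditions.

Discrimination is summarized by the rank-statistic AUC (midrank tie
handling) on both the training and held-out evaluation sets.

## Interpreting the model

Partial dependence at temperature *t* is the mean predicted occurrence
probability over all observed covariate rows with temperature forced to
*t*; the implementation is batch-vectorized and verified to equal the
brute-force row loop to 1e-10. Variable importance is gain, extracted per
bootstrap iteration and summarized by medians and full ranges.

Field thermal extrema follow empirical-derivative rules on the PDP:

- **Thermal minimum (persistent rise)** — the first grid point whose
  forward difference is strictly positive and stays strictly positive for
  the next step as well. Strictness matters: flat segments must not trigger
  an onset.
- **Thermal minimum (steepest)** — the grid point with the largest forward
  difference (lowest temperature on ties).
- **Thermal optimum** — the grid temperature of the curve maximum, lowest
  temperature on exact ties; flagged absent when the maximum sits at the
  final grid point (a boundary maximum carries no evidence of an interior
  optimum). No thermal maximum is extracted anywhere: occurrence curves
  rarely resolve upper-limit structure.

Numerical choice that matters: the extraction grid defaults to 40 evenly
spaced points over the pooled presence + background temperature range,
deliberately coarser than the 100-point default used for plotting curves.
A boosted ensemble's PDP is piecewise constant; with a grid much finer
than the ensemble's step spacing, forward differences are mostly zero and
the persistent-rise rule fires at whatever isolated mid-slope step first
repeats, inflating the minimum by several °C. With the coarser grid the
median recovered minimum lands within about ±1.6 °C of the planted truth
across world seeds at the desk scale.

### Known limitation: optimum extraction on plateaued curves

CV-tuned desk-scale ensembles frequently predict *exactly* equal
probabilities over a broad band around the optimum (no split survives the
tuned regularization where the suitability curve is flat), so the
lowest-temperature tie-break returns the plateau's left edge and the
extracted optimum runs 3–8 °C cool even though the training data localize
the peak correctly. The bias is robust to grid resolution and persists
across bootstrap iterations (they share the data). Users should treat
field-derived optima as lower bounds at small data scales — an echo of the
well-known difficulty of reading thermal optima and maxima from
distributional data, where field optima have been observed to sit several
degrees below laboratory ones.

## The mechanistic side

Traits use the field's standard forms: Briere-1
$c\,T\,(T - T_0)\sqrt{T_m - T}$ for development rate; concave-down
quadratics $q\,(T - T_0)(T_m - T)$ (truncated at zero) for fecundity and
egg-to-adult survival; a concave-up quadratic $q\,(T - T_0)(T - T_m)$ for
adult mortality. In the composition the mortality rate is clamped below at
`mu_floor` (default 1e-3 day⁻¹) to prevent division blow-up where the
concave-up quadratic approaches zero; the clamp's activity share is
reported on every curve. $M(T)$ is set to zero wherever any numerator
trait is non-positive, making its support the intersection of the
numerator supports — so the per-draw thermal minimum equals the largest
numerator $T_0$ and the maximum the smallest numerator $T_m$, up to one
0.1 °C grid step (a tested invariant).

Pseudo-posterior draws add Gaussian noise (SD = `dispersion`, in °C) to the
thermal thresholds and lognormal noise (sdlog = 0.05 × dispersion) to the
scale parameters, redrawing any invalid pair ($T_0 \ge T_m$); zero
dispersion collapses to the truth. Draws are combined across traits by
index, i.e. treated as independent across traits — no cross-trait posterior
coupling is imposed. The shipped trait parameter sets are **synthetic
placeholders** chosen for biological plausibility; they are not fitted
posteriors for any real species. `trait_params_for_truth()` calibrates a
trait set whose composed $M(T)$ matches a requested (Tmin, Topt, Tmax) by a
one-dimensional numerical shift of the quadratic centers, which is how the
lab side is matched to a planted field truth in recovery studies.

## Comparison and sensitivity

Curves are min–max scaled to [0, 1] for plotting (constant curves scale to
zeros with a warning). Across species, the Pearson correlation is computed
between median lab and median field minima, and separately for optima, with
pairwise (not listwise) deletion of species missing one side, mirroring how
each quantity is available for a different subset of species. Differences
are reported as lab minus field in °C. Regional-exclusion refits drop
occurrences and background candidates inside given bounding boxes and rerun
the whole chain under the same master seed; an empty exclusion reproduces
the baseline byte-for-byte, which is also the pipeline's determinism test.

## Numerical and degenerate-input conventions

- Cell membership is half-open in both axes; boundary points belong to one
  cell, deterministically.
- All generators and the pipeline are pure functions of (config, seed);
  child seeds derive from the master seed.
- Zero-variance features are reported by the collinearity screen, not
  dropped; the screen itself is advisory.
- A single-class evaluation set, an empty PDP grid, a non-ascending grid,
  zero-variance correlation inputs, all-zero sampling probabilities, and an
  exhausted background pool are all hard, named errors.
- Constant PDP curves yield absent extrema; all-undefined summaries return
  an absent result with a reason rather than NaN.

## Limitations

Beyond the optimum-plateau bias above: the synthetic world's planar
distances and cell-box "polygons" are desk-scale conveniences, not
geodesy; the background scheme implements only the ecoregion + bias-mask
design (no target-group or distance-decay variants); there is no spatial
cross-validation (splits are random, as in the study design this package
follows); and nothing here should be extrapolated to climate-projection
use — the field side cannot see upper thermal limits that current
distributions do not express.
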