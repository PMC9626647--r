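---
title: "Two-step gap-filling of ocean-color fields and ensemble bloom phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step gap-filling of ocean-color fields and ensemble bloom phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomfill)
```

## The model

Satellite chlorophyll-a fields lose a large, seasonally varying fraction of
their pixels to cloud cover — up to ~40% during a summer monsoon — and every
single-value gap-filling technique (interpolation, EOF reconstruction,
climatological substitution) hides how much those gaps matter for any
statistic computed downstream. `bloomfill` treats gap-filling as *multiple
imputation*: after a deliberately conservative interpolation pass, every
remaining missing pixel is filled with N independent pseudo-random draws
from that grid cell's estimated probability distribution, producing N
complete fields that agree exactly wherever data exist. The spread of any
derived quantity across the N members is the uncertainty attributable to
the missing data.

### Step I — optimal linear interpolation

A missing pixel is replaced by the equally weighted arithmetic mean of its
two *immediate* neighbours along one axis; an invalid neighbour (land,
missing, or beyond the domain edge) receives zero weight, and when both
neighbours are invalid the gap is left unfilled. The pass is applied along
longitude, then latitude, then time, each pass operating on the output of
the previous one. The ordering follows the spatial anisotropy of bloom
fields — zonal variation is weaker than meridional, and week-to-week
temporal variation is strongest — and `pass_rmse()` verifies it empirically
by holdout cross-validation (withhold 10% of observed pixels, predict each
from its two axis neighbours, score only pixels that retain both
neighbours, where the two-point rule is unbiased).

Two details are deliberate. The stencil is never widened beyond the
immediate neighbours: wider averaging blends sub-grid bloom patchiness and
biases concentrations. And within a pass all fills are computed
simultaneously from the pre-pass state, so a newly filled value never seeds
another fill in the same pass; this makes each pass deterministic and
independent of scan order. There is no longitudinal wrap-around (the
intended domain is a regional basin, not the globe).

### Step II — per-cell distributions and Monte-Carlo imputation

Each cell's valid values, pooled over the full time axis (all seasons, all
years — one marginal distribution per grid point, with no seasonal
conditioning), are fitted with three parametric candidates by maximum
likelihood:

* normal (location = mean, scale = population SD),
* lognormal and gamma in shape/location/scale form, with the location
  (lower-bound shift) estimated by profile likelihood under the constraint
  0 ≤ location < min(sample), since chlorophyll is positive.

A one-sample Kolmogorov–Smirnov test scores each candidate; the family with
the largest p-value is selected if that p ≥ 0.05, and otherwise the cell
falls back to a Gaussian-kernel density estimate whose bandwidth maximises
the held-out log-density over 5-fold cross-validation (20 log-spaced
candidates spanning 0.1–10 × Silverman's rule-of-thumb bandwidth, seeded
fold shuffle). The KDE fallback is what handles multimodal cells — e.g. a
bimodal background/bloom mixture — that no single parametric family can
represent.

Two statistical caveats are intentional properties of the procedure rather
than oversights. The K-S p-values are computed from the standard asymptotic
distribution even though the parameters were estimated from the same sample,
which is anticonservative; the test is used as a *relative* score among
candidates, not as a calibrated hypothesis test. And draws are independent
across pixels and members — the per-grid marginal scheme carries no spatial
or temporal correlation into the imputed noise; correlated (e.g.
Markov-chain) imputation is out of scope.

Imputation then fills every remaining gap with `n_members` draws (default
N = 10,000) from the cell's distribution. Positivity is enforced by
rejection sampling (non-positive normal/KDE draws are redrawn, up to 1000
rounds, then clipped to the cell's minimum observed value; clipping is
logged). Each pixel owns a private random substream derived by a
deterministic integer hash of (master seed, time, lat, lon), so results are
independent of traversal order, members can be regenerated lazily from the
seed, and two runs with the same seed are bit-identical.

### Phenology by the threshold method

For a complete (gap-filled) year of composites, *bloom initiation* is the
first composite whose value strictly exceeds 1.05 × the annual median
(i.e. 5% above it), and the *bloom peak* is the maximum composite within
the summer window (months 6–9 by default; ties resolve to the earliest
composite). Both are computed per ensemble member; the summary reports the
min/mean/max dates (mean over members with a detected event, rounded to
the nearest composite) and the fraction of members with no detection.

One design choice deserves emphasis: the annual median is always computed
over the whole year, but the initiation scan defaults to the summer months
(`init_months = summer_months`). In a region with a secondary winter bloom,
a scan starting 1 January declares "initiation" on the decaying tail of the
winter bloom — or, on noisy series, on the first composite that noise
pushes 5% above the median, which happens within the first few composites
with near certainty at realistic noise levels. Restricting the scan to the
season whose bloom the indicator targets makes it measure that bloom;
`init_months = 1:12` restores a whole-year scan, and the low-level
`bloom_initiation()` takes any explicit index window. No persistence above
the threshold is required (a single exceedance triggers), and the
exceedance is strict.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_ensembles` | 10000 | members | imputation ensemble size N |
| `threshold_factor` | 1.05 | – | initiation threshold over annual median |
| `summer_months` | 6–9 | months | peak search and default initiation scan |
| minimum fitting sample | 8 | values | below it a cell is reported `unfit` and left to Step I only (MLE and CV are unstable on smaller samples) |
| K-S rejection level | 0.05 | – | all-parametric-rejected ⇒ KDE fallback |
| CV folds / bandwidth grid | 5 / 20 | – | KDE bandwidth selection |
| degenerate-sample bandwidth | max(1e-6, 1e-3·c) | data units | zero-variance cell centred at constant c |
| composite length | 8 | days | windows restart each 1 January ⇒ 46/year |

## What the synthetic generator emulates — and what it does not

`simulate_chl_field()` builds a noise-free curve per pixel,
`g(lat, lon) · (baseline + summer bump + winter bump)`, and multiplies it by
lognormal noise `exp(ε)`, `ε ~ N(0, σ²)`, σ = 0.3 by default — enough to
make the raw-scale values right-skewed, as real composites are. The spatial
factor `g` combines a meridional gradient (stronger than the zonal one), a
banded meridional sine, and a coastal enhancement; background and bloom
amplitudes share this pattern, so coastal/northern blooms are stronger. The
banding matters for testing: a purely linear gradient is interpolated
*exactly* by the two-point mean, so only meridional curvature produces the
RMSE(lon) < RMSE(lat) ordering the pass sequence relies on. Timing is a
mid-July summer bloom and a smaller mid-January winter bloom, matching the
two-bloom monsoon annual cycle. The true initiation/peak per pixel-year are
obtained by applying the threshold operators to the noise-free curve.

`apply_cloud_gaps()` thresholds Gaussian-smoothed latent noise fields that
evolve as an AR(1) process across composites. The defaults — smoothing
2.5 cells, persistence 0.95 — produce synoptic-scale decks with mean gap
runs of ~20 composites, i.e. cloud cover that blankets much of the basin
for most of a monsoon season. These values were chosen so that a
substantial share of the summer gaps survives the neighbour-interpolation
step and actually reaches the Monte-Carlo step, as happens in real
monsoon-season fields; with short-lived, small gaps Step I resolves nearly
everything and Step II has nothing to quantify. Order-statistic
thresholding pins each composite's achieved gap fraction to its seasonal
target (40% in June–September, 10% otherwise, by default) up to
pixel-count rounding.

Passing tests on this generator show that the algorithm recovers fields
whose gaps are *marginally* exchangeable with the observed values at each
cell. Real ocean-color data violate that in ways the generator does not
emulate: gaps correlate with the geophysical state (clouds accompany the
monsoon bloom itself, so missing values are not missing-at-random),
retrieval noise is heteroscedastic and spatially correlated, and coastal
cells mix optically complex waters. Recovery scores here are therefore an
upper bound on real-data performance.

## What the ensemble uncertainty does and does not cover

The members differ *only* at Monte-Carlo-imputed pixels. Consequently the
ensemble range quantifies imputation uncertainty alone: it contains no
contribution from observation noise or from the deterministic Step-I
interpolation error. The practical consequence, measured on synthetic data
(25% summer gaps, 200 members), is that the ensemble initiation range
brackets the initiation that a *complete observed* series would have given
in ~84% of pixels, but brackets the initiation of the *noise-free* truth
curve in only ~46% — at pixels whose initiation-deciding composites are
observed, the range collapses to a point, and multiplicative noise shifts
the first threshold crossing about half the time. This is inherent to the
method (single-exceedance threshold, shared observed pixels), not to the
implementation; the package documents the range as "uncertainty due to
missing data", which is exactly what it is.

## Numerical choices and degenerate inputs

* Profile-likelihood location fits are bounded at 0.95 × min(sample):
  shifted lognormal/gamma likelihoods have a singularity as the shift
  approaches the sample minimum, and the bound keeps the optimiser on the
  interior optimum (the location-0 endpoint is always evaluated and kept
  when better).
* The gamma shape MLE uses the standard closed-form initial guess refined
  by Newton steps on the digamma equation; a zero-variance sample maps to
  the large-shape (near-degenerate) limit.
* Peak ties resolve to the earliest composite; initiation uses strict
  inequality; the mean date across members is the arithmetic mean of
  composite indices rounded to the nearest composite start.
* Conservative regridding weights fine cells by cos(latitude); a coarse
  pixel is valid as soon as one valid fine cell contributes, and is land
  only if all its fine cells are land.
* A coarse cell with fewer than 8 valid composites over the whole record
  is reported `unfit`; its gaps are filled by Step I only and flagged if
  any remain.
* 8-day windows restart every 1 January (46 per year; the last window has
  5 or 6 days), so composite indices are comparable across years and leap
  years shift nothing.

## Problem sizes used in the tests

The suite exercises the full chain on a 12 × 12 grid (10 × 10 ocean inside
a land border), 3 years × 46 composites, with 200-member ensembles for the
recovery and phenology checks and 10,000 members where the ensemble-size
default itself is under test; distribution-selection accuracy uses 200
replicates of n = 2000 per family. These sizes give stable statistics for
every property tested while keeping the whole suite fast enough to run
routinely.

## Known limitations

* No spatial or temporal correlation in imputed noise (per-grid marginal
  PDFs); no seasonally conditioned distributions.
* K-S p-values are anticonservative for estimated parameters (no
  Lilliefors correction), as in the procedure the package reproduces.
* Step-I interpolation error and observation noise are not part of the
  reported uncertainty (see above).
* The threshold method is sensitive to single-composite noise excursions;
  with a whole-year scan on noisy series it effectively measures the first
  noise exceedance, which is why the initiation scan defaults to the
  summer window.
* Regridding requires the coarse cell size to be an integer multiple of
  the fine spacing (conservative binning on nesting grids only).
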