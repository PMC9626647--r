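# bloomfill

Gap-filling of gridded satellite ocean-color (chlorophyll-a) time series by
Monte-Carlo multiple imputation, with phytoplankton-bloom phenology and its
uncertainty.

## The problem

Satellite chlorophyll fields are riddled with gaps from cloud cover,
sun-glint and sensor dropouts. Over monsoon regions the summer-season loss
reaches ~40% of pixels — precisely when the main phytoplankton bloom occurs —
so phenology indicators (when did the bloom start? when did it peak?)
computed from the raw fields are biased or undefined. Conventional fixes
(interpolation, DINEOF, climatological substitution) impute a *single* value
per gap and therefore say nothing about how much the missing data matter.

`bloomfill` implements a two-step alternative for users of gridded
ocean-color products (8-day composites on a regular 1° grid):

1. **Optimal linear interpolation** — a missing pixel is replaced by the
   equally weighted mean of its two immediate neighbours, applied
   sequentially along longitude, latitude, then time. An invalid neighbour
   (land or missing) gets zero weight; if both neighbours are invalid the
   gap is left unfilled. The stencil is deliberately never widened.
2. **Monte-Carlo multiple imputation** — each grid cell's valid values
   (pooled over the full record) are fitted with normal, lognormal and gamma
   candidates by maximum likelihood; a one-sample Kolmogorov–Smirnov test
   scores each fit and the largest p-value wins, provided p ≥ 0.05 —
   otherwise the cell falls back to a Gaussian-kernel density estimate with
   cross-validated bandwidth. Every remaining gap is then filled with N
   (default 10,000) pseudo-random draws from the cell's PDF, giving an
   ensemble of N gap-free fields that agree at every observed pixel.

Any statistic computed across the ensemble — here, bloom initiation (first
summer composite exceeding 1.05 × the annual median) and bloom peak (summer
maximum) — comes with a min/mean/max range that quantifies the uncertainty
caused by the missing data.

A seeded synthetic-data module generates truth fields with known phenology
(two annual blooms, coastal and meridional gradients, multiplicative
lognormal noise) plus realistic seasonally varying, spatially correlated
cloud-gap masks, so the whole chain is testable without any satellite
download.

## Worked example

```r
library(bloomfill)

# a 3-year synthetic basin with 40% summer / 10% off-season cloud gaps
truth  <- simulate_chl_field(seed = 4)
gapped <- apply_cloud_gaps(truth, summer_gap = 0.4, offseason_gap = 0.1, seed = 5)
gap_fraction(gapped)
#> <gap_report> 20.43% missing over 100 ocean pixels, 138 composites

# Step I: sequential two-neighbour interpolation (lon -> lat -> time)
step1 <- optimal_interpolate(gapped)
gap_fraction(step1)
#> <gap_report> 5.43% missing over 100 ocean pixels, 138 composites

# Step II: per-cell PDF selection and a 200-member imputation ensemble
fits <- fit_field(step1)
ens  <- generate_ensembles(step1, fits$fits, n_members = 200, seed = 9)
gap_fraction(ensemble_member(ens, 1))
#> <gap_report> 0.00% missing over 100 ocean pixels, 138 composites

# bloom phenology with uncertainty at a cell under the summer cloud deck
ensemble_phenology(ens, 1999, cell = c(6, 3))
#> <phenology_summary> year 1999 (200 members)
#>   initiation: 10 Jun .. 28 Jul (mean 18 Jun; undetected in 0% of members)
#>   peak:       10 Jun .. 22 Sep (mean 20 Jul)
```

The gap report shows the two-step reduction (20.4% → 5.4% → 0%). The
phenology summary reads: across the 200 gap-filled realizations of this
cell — which loses much of its summer to a persistent simulated cloud
deck — the bloom initiation falls between 10 June and 28 July (mean 18
June) and the peak between 10 June and 22 September (mean 20 July); the
width of each range is the uncertainty attributable to the imputed pixels,
and at fully observed cells it collapses to zero.

`run_pipeline(default_config(...))` drives the full chain (compositing,
regridding, both filling steps, phenology, netCDF/CSV/JSON outputs), and
`inst/cli/bloomfill` exposes it as a command line
(`simulate | composite | regrid | fill | phenology | pipeline`).

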