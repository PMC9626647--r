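#' @name synthetic_data
#' @title Seeded synthetic chlorophyll fields with known phenology
#' @description
#' A simulator of gap-free "truth" chlorophyll fields that reproduces the
#' statistical structure the gap-filling method is designed for: a
#' positive, right-skewed field with two annual blooms (a large summer
#' bloom and a smaller winter one), coastal-to-open-ocean and
#' north-south spatial gradients, a land border, and seasonally varying,
#' spatially correlated cloud gaps. Because the generating curve is
#' known, the true bloom initiation and peak are known exactly, which is
#' what makes end-to-end recovery tests possible without any satellite
#' download.
NULL

#' Default simulator parameters
#'
#' The defaults describe a small monsoon-like basin: a 10 x 10 ocean grid
#' inside a one-cell land border, 3 years of 46 8-day composites, a
#' summer bloom peaking in mid-July (amplitude 2 mg/m3 over a 0.3 mg/m3
#' background) and a secondary winter bloom about 40% as strong peaking
#' in mid-January, as the monsoon-driven two-bloom annual cycle of the
#' region has. The spatial gradient is deliberately stronger
#' meridionally than zonally — the situation that motivates interpolating
#' longitude first — and chlorophyll is enhanced towards the coast.
#' Multiplicative lognormal noise with sigma = 0.3 makes the raw-scale
#' values right-skewed, as ocean-color data is.
#'
#' @param ... overrides for any default.
#' @return Named list of generator parameters.
#' @export
synth_params <- function(...) {
  p <- list(
    n_lat = 12L, n_lon = 12L,       # incl. one-cell land border
    years = 3L, start_year = 1998L,
    lat0 = 0, lon0 = 60, cell_deg = 1,
    baseline = 0.3,                 # open-ocean background, mg/m3
    coastal_amp = 0.5, coastal_scale = 2,     # e-folding in cells
    grad_lat = 1.0, grad_lon = 0.2, # relative gradient across the basin
    merid_wave_amp = 0.3, merid_wave_cycles = 1.5,  # banded meridional structure
    summer_amp = 2.0, summer_peak_yday = 200, summer_width = 20,
    winter_amp = 0.8, winter_peak_yday = 15, winter_width = 20,
    noise_sigma = 0.3)
  over <- list(...)
  p[names(over)] <- over
  p
}

# circular day-of-year distance
yday_dist <- function(yd, center) {
  d <- abs(yd - center)
  pmin(d, 365 - d)
}

# Chebyshev distance to the nearest land cell, in grid cells
dist_to_land <- function(land) {
  d <- dim(land)
  out <- matrix(Inf, d[1], d[2])
  lands <- which(land, arr.ind = TRUE)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (land[i, j]) { out[i, j] <- 0; next }
    out[i, j] <- min(pmax(abs(lands[, 1] - i), abs(lands[, 2] - j)))
  }
  out
}

#' Simulate a gap-free chlorophyll truth field
#'
#' Per pixel and composite, the noise-free curve is
#' `g(lat, lon) * (baseline + summer bump + winter bump)`, with Gaussian
#' bumps in day-of-year (circular, so the winter bloom wraps the year
#' boundary) and `g` combining linear meridional/zonal gradients, a
#' banded meridional sine, and a coastal enhancement; background and
#' bloom amplitudes share the spatial pattern. Observed values multiply the curve by
#' `exp(eps)`, `eps ~ N(0, noise_sigma^2)`, so the field is strictly
#' positive and right-skewed. True phenology is computed by applying the
#' threshold-method operators to the noise-free curve.
#'
#' @param params list from [synth_params()].
#' @param seed integer seed.
#' @return An object of class `synthetic_truth`: `field` (gap-free
#'   [gridded_field]), `curve` (noise-free array), `params`, and
#'   `truth_phenology` (data.frame: lat_idx, lon_idx, year,
#'   initiation_index, peak_index, initiation_date, peak_date).
#' @export
simulate_chl_field <- function(params = synth_params(), seed = 1L) {
  p <- params
  if (p$summer_amp <= 0 || p$winter_amp <= 0 || p$baseline <= 0)
    stop("baseline and bloom amplitudes must be positive")
  if (p$noise_sigma < 0) stop("noise_sigma must be >= 0")
  land <- matrix(FALSE, p$n_lat, p$n_lon)
  land[c(1, p$n_lat), ] <- TRUE
  land[, c(1, p$n_lon)] <- TRUE
  lat <- p$lat0 + (seq_len(p$n_lat) - 0.5) * p$cell_deg
  lon <- p$lon0 + (seq_len(p$n_lon) - 0.5) * p$cell_deg
  years <- p$start_year + seq_len(p$years) - 1L
  time <- as.Date(unlist(lapply(years, function(y)
    as.character(as.Date(sprintf("%d-01-01", y)) + 8L * 0:45))))
  yd <- as.integer(format(time, "%j"))
  n_t <- length(time)

  dl <- dist_to_land(land)
  latn <- (seq_len(p$n_lat) - 1) / (p$n_lat - 1)
  lonn <- (seq_len(p$n_lon) - 1) / (p$n_lon - 1)
  # meridional structure is both stronger (gradient) and rougher (banded
  # sine) than the zonal one; the two-point mean is exact on a linear
  # gradient, so the bands are what gives latitude interpolation its
  # larger RMSE, as the meridional patchiness of real blooms does
  g <- (1 + p$grad_lat * outer(latn, rep(1, p$n_lon)) +
          p$grad_lon * outer(rep(1, p$n_lat), lonn) +
          p$merid_wave_amp * outer(sin(2 * pi * p$merid_wave_cycles * latn),
                                   rep(1, p$n_lon))) *
    (1 + p$coastal_amp * exp(-dl / p$coastal_scale))

  seasonal <- p$summer_amp * exp(-yday_dist(yd, p$summer_peak_yday)^2 /
                                   (2 * p$summer_width^2)) +
    p$winter_amp * exp(-yday_dist(yd, p$winter_peak_yday)^2 /
                         (2 * p$winter_width^2))
  # per-pixel bloom amplitudes follow the same spatial pattern as the
  # background: coastal and northern blooms are stronger, as in the basin
  # the generator emulates
  curve <- outer(p$baseline + seasonal, g)

  noise <- with_seed(seed,
    array(exp(rnorm(n_t * p$n_lat * p$n_lon, 0, p$noise_sigma)),
          c(n_t, p$n_lat, p$n_lon)))
  field <- gridded_field(curve * noise, time, lat, lon, land = land)

  # true phenology from the noise-free curve, one row per ocean pixel-year
  rows <- list()
  for (y in years) {
    t_idx <- which(as.integer(format(time, "%Y")) == y)
    for (i in seq_len(p$n_lat)) for (j in seq_len(p$n_lon)) {
      if (land[i, j]) next
      bi <- bloom_indices(curve[t_idx, i, j], time[t_idx])
      rows[[length(rows) + 1L]] <- data.frame(
        lat_idx = i, lon_idx = j, lat = lat[i], lon = lon[j], year = y,
        initiation_index = bi$initiation_index, peak_index = bi$peak_index,
        initiation_date = bi$initiation_date, peak_date = bi$peak_date)
    }
  }
  structure(list(field = field, curve = curve, params = p,
                 truth_phenology = do.call(rbind, rows)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d x %d grid, %d years, noise sigma %.2f\n",
              x$params$n_lat, x$params$n_lon, x$params$years,
              x$params$noise_sigma))
  invisible(x)
}

# separable Gaussian smoothing with edge renormalisation
smooth2d <- function(m, sd) {
  r <- max(1L, ceiling(3 * sd))
  k <- dnorm(-r:r, sd = sd)
  pass <- function(x) {
    n <- nrow(x)
    out <- matrix(0, n, ncol(x)); wsum <- out
    for (o in -r:r) {
      src <- seq_len(n) + o
      keep <- src >= 1 & src <= n
      w <- k[o + r + 1]
      out[keep, ] <- out[keep, ] + w * x[src[keep], ]
      wsum[keep, ] <- wsum[keep, ] + w
    }
    out / wsum
  }
  t(pass(t(pass(m))))
}

#' Impose seasonal, spatially correlated cloud gaps
#'
#' Builds a missing-observation mask from Gaussian-smoothed latent noise
#' fields that evolve as an AR(1) process across composites
#' (`persistence` is the lag-1 correlation), thresholded each composite
#' at the season's target gap fraction. Smoothing produces contiguous
#' cloud-deck-like blobs; the AR(1) evolution makes gaps persist over
#' consecutive composites, as monsoon cloud cover does; order-statistic
#' thresholding pins the achieved per-composite fraction to the target
#' up to pixel-count rounding.
#'
#' @param truth a `synthetic_truth` (or a gap-free [gridded_field]).
#' @param summer_gap target missing fraction in summer composites
#'   (default 0.4).
#' @param offseason_gap target missing fraction elsewhere (default 0.1).
#' @param summer_months months counted as summer (default June-Sept).
#' @param persistence AR(1) coefficient of the latent field in \[0, 1\]
#'   (default 0.95: a mean gap-run length of ~20 composites, i.e. a deck
#'   persisting for most of a monsoon season).
#' @param smooth_sd spatial smoothing scale of the latent noise, in grid
#'   cells (default 2.5: synoptic-scale decks covering a large fraction
#'   of the basin, so that a substantial share of the gaps survives the
#'   neighbour-interpolation step and reaches the Monte-Carlo step, as
#'   in the real monsoon-season fields).
#' @param seed integer seed (independent of the truth seed).
#' @return A [gridded_field] equal to the truth with the masked pixels
#'   set missing.
#' @export
apply_cloud_gaps <- function(truth, summer_gap = 0.4, offseason_gap = 0.1,
                             summer_months = 6:9, persistence = 0.95,
                             smooth_sd = 2.5, seed = 2L) {
  field <- if (inherits(truth, "synthetic_truth")) truth$field else truth
  stopifnot(inherits(field, "gridded_field"))
  if (summer_gap < 0 || summer_gap >= 1 || offseason_gap < 0 || offseason_gap >= 1)
    stop("gap fractions must lie in [0, 1)")
  if (persistence < 0 || persistence > 1)
    stop("persistence must lie in [0, 1]")
  d <- dim(field$values)
  in_summer <- seq_len(d[1]) %in% month_window(field$time, summer_months)
  target <- ifelse(in_summer, summer_gap, offseason_gap)
  ocean <- !field$land
  n_ocean <- sum(ocean)
  missing <- array(FALSE, d)
  with_seed(seed, {
    z <- smooth2d(matrix(rnorm(d[2] * d[3]), d[2], d[3]), smooth_sd)
    for (t in seq_len(d[1])) {
      if (t > 1) {
        eps <- smooth2d(matrix(rnorm(d[2] * d[3]), d[2], d[3]), smooth_sd)
        z <- persistence * z + sqrt(1 - persistence^2) * eps
      }
      k <- round(target[t] * n_ocean)
      if (k > 0) {
        zo <- z[ocean]
        thr <- sort(zo, decreasing = TRUE)[k]
        mt <- matrix(FALSE, d[2], d[3])
        mt[ocean] <- z[ocean] >= thr
        missing[t, , ] <- mt
      }
    }
  })
  vals <- field$values
  vals[missing] <- NA_real_
  gridded_field(vals, field$time, field$lat, field$lon,
                land = field$land, missing = missing)
}
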