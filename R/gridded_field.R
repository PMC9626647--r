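#' Gridded chlorophyll field
#'
#' The central container of the package: a 3-D array of surface
#' chlorophyll-a concentration (mg/m3) on a regular latitude-longitude
#' grid, together with a missing-observation mask and a static land mask.
#' Land is kept distinct from missing: a land pixel is *invalid* and is
#' never filled, while a missing ocean pixel is a gap that the two-step
#' algorithm reconstructs.
#'
#' @param values numeric array with dimensions (time, lat, lon). `NA`
#'   marks pixels without an observation (and land pixels).
#' @param time vector of class `Date`, strictly increasing; for 8-day
#'   composites these are composite start dates.
#' @param lat,lon numeric cell-centre coordinates in degrees, regularly
#'   spaced.
#' @param land logical matrix (lat, lon); `TRUE` marks land.
#' @param missing optional logical array (time, lat, lon) marking missing
#'   ocean observations. Defaults to `is.na(values)` outside land.
#'
#' @return An object of class `gridded_field` with elements `values`
#'   (`NA` wherever missing or land), `missing`, `land`, `time`, `lat`,
#'   `lon`.
#'
#' @details Invariants enforced at construction: values are strictly
#'   positive wherever observed; land pixels carry no data and are never
#'   flagged missing; the time axis is strictly increasing; all shapes
#'   are consistent.
#' @export
gridded_field <- function(values, time, lat, lon, land = NULL, missing = NULL) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array (time, lat, lon)")
  dims <- dim(values)
  if (dims[1] != length(time) || dims[2] != length(lat) || dims[3] != length(lon))
    stop("dimensions of `values` do not match time/lat/lon lengths")
  time <- as.Date(time)
  if (any(diff(as.numeric(time)) <= 0))
    stop("`time` must be strictly increasing")
  if (is.null(land)) land <- matrix(FALSE, dims[2], dims[3])
  if (!identical(dim(land), dims[2:3]))
    stop("`land` must be a (lat, lon) matrix matching `values`")
  land_arr <- aperm(array(land, c(dims[2], dims[3], dims[1])), c(3, 1, 2))
  values[land_arr] <- NA_real_
  if (is.null(missing)) {
    missing <- is.na(values) & !land_arr
  } else {
    if (!identical(dim(missing), dims))
      stop("`missing` must match the shape of `values`")
    missing <- missing & !land_arr
    values[missing] <- NA_real_
  }
  obs <- values[!is.na(values)]
  if (length(obs) && any(obs <= 0))
    stop("observed chlorophyll values must be strictly positive")
  structure(
    list(values = values, missing = missing, land = land,
         time = time, lat = as.numeric(lat), lon = as.numeric(lon)),
    class = "gridded_field"
  )
}

#' @export
print.gridded_field <- function(x, ...) {
  d <- dim(x$values)
  n_ocean <- sum(!x$land)
  cat(sprintf("<gridded_field> %d composites x %d lat x %d lon\n", d[1], d[2], d[3]))
  cat(sprintf("  time: %s .. %s\n", format(x$time[1]), format(x$time[d[1]])))
  cat(sprintf("  ocean pixels: %d (land: %d)\n", n_ocean, sum(x$land)))
  cat(sprintf("  missing ocean obs: %.1f%%\n",
              100 * sum(x$missing) / max(1, n_ocean * d[1])))
  invisible(x)
}

# land mask broadcast to the (time, lat, lon) shape of a field
land_cube <- function(field) {
  d <- dim(field$values)
  aperm(array(field$land, c(d[2], d[3], d[1])), c(3, 1, 2))
}

#' Build 8-day composites from a daily field
#'
#' Averages valid daily observations inside consecutive 8-day windows.
#' Windows restart every January 1 (the standard ocean-color convention),
#' giving 46 composites per year; the final window of a year holds 5 or 6
#' days. A composite pixel is missing iff no day in its window was
#' observed.
#'
#' @param daily a [gridded_field] with a time axis at 1-day spacing.
#' @return A [gridded_field] of 8-day composites; the time axis holds the
#'   window start dates.
#' @export
compose_8day <- function(daily) {
  stopifnot(inherits(daily, "gridded_field"))
  if (any(diff(as.numeric(daily$time)) != 1))
    stop("compose_8day() requires a daily time axis (1-day spacing)")
  yr <- as.integer(format(daily$time, "%Y"))
  yd <- as.integer(format(daily$time, "%j"))
  win <- (yd - 1L) %/% 8L                      # 0..45 within the year
  key <- yr * 100L + win
  groups <- unique(key)                        # time is sorted, so keys are too
  d <- dim(daily$values)
  out <- array(NA_real_, c(length(groups), d[2], d[3]))
  starts <- as.Date(rep(NA, length(groups)))
  for (g in seq_along(groups)) {
    idx <- which(key == groups[g])
    sub <- daily$values[idx, , , drop = FALSE]
    valid <- !is.na(sub)
    cnt <- apply(valid, c(2, 3), sum)
    s <- apply(sub, c(2, 3), function(v) sum(v, na.rm = TRUE))
    m <- s / cnt
    m[cnt == 0] <- NA_real_
    out[g, , ] <- m
    starts[g] <- as.Date(sprintf("%d-01-01", groups[g] %/% 100L)) +
      8L * (groups[g] %% 100L)
  }
  gridded_field(out, starts, daily$lat, daily$lon, land = daily$land)
}

#' Conservative regridding to a coarser resolution
#'
#' Area-weighted (conservative) binning of a fine regular grid into coarse
#' cells of `target_cell_deg` degrees. Cell areas on the sphere are
#' proportional to cos(latitude), which supplies the weights. A coarse
#' pixel is valid as soon as one valid non-land fine cell contributes;
#' it is land only when every contributing fine cell is land.
#'
#' @param fine a [gridded_field] on the fine grid.
#' @param target_cell_deg coarse cell size in degrees; must be an integer
#'   multiple of the fine spacing, and the fine grid extent must tile into
#'   whole coarse cells.
#' @return A [gridded_field] on the coarse grid.
#' @export
regrid_conservative <- function(fine, target_cell_deg) {
  stopifnot(inherits(fine, "gridded_field"))
  res_lat <- diff(fine$lat)[1]
  res_lon <- diff(fine$lon)[1]
  f_lat <- target_cell_deg / res_lat
  f_lon <- target_cell_deg / res_lon
  ok <- function(f) abs(f - round(f)) < 1e-8 && round(f) >= 1
  if (!ok(f_lat) || !ok(f_lon))
    stop("target resolution is not an integer multiple of the fine grid spacing")
  f_lat <- as.integer(round(f_lat)); f_lon <- as.integer(round(f_lon))
  d <- dim(fine$values)
  if (d[2] %% f_lat != 0 || d[3] %% f_lon != 0)
    stop("fine grid does not tile into whole coarse cells")
  n_lat <- d[2] %/% f_lat; n_lon <- d[3] %/% f_lon
  w_lat <- cos(fine$lat * pi / 180)
  out <- array(NA_real_, c(d[1], n_lat, n_lon))
  land <- matrix(FALSE, n_lat, n_lon)
  for (ci in seq_len(n_lat)) {
    ri <- ((ci - 1L) * f_lat + 1L):(ci * f_lat)
    for (cj in seq_len(n_lon)) {
      rj <- ((cj - 1L) * f_lon + 1L):(cj * f_lon)
      land[ci, cj] <- all(fine$land[ri, rj])
      block <- fine$values[, ri, rj, drop = FALSE]
      m <- matrix(block, nrow = d[1])               # time x (f_lat*f_lon)
      w <- rep(w_lat[ri], times = f_lon)            # fine-cell areas
      valid <- !is.na(m)
      m0 <- m; m0[!valid] <- 0
      den <- valid %*% w
      num <- m0 %*% w
      v <- num / den
      v[den == 0] <- NA_real_
      out[, ci, cj] <- v
    }
  }
  coarse_lat <- vapply(seq_len(n_lat), function(ci)
    mean(fine$lat[((ci - 1L) * f_lat + 1L):(ci * f_lat)]), numeric(1))
  coarse_lon <- vapply(seq_len(n_lon), function(cj)
    mean(fine$lon[((cj - 1L) * f_lon + 1L):(cj * f_lon)]), numeric(1))
  gridded_field(out, fine$time, coarse_lat, coarse_lon, land = land)
}

#' Gap statistics for a field
#'
#' Per-pixel missing fraction over a time subset, plus the basin summary
#' (mean over ocean pixels). Land pixels are excluded from all
#' denominators and carry `NA` in the per-pixel map.
#'
#' @param field a [gridded_field].
#' @param time_subset integer indices into the time axis (default: all).
#' @return An object of class `gap_report`: list with `fraction` (lat x
#'   lon matrix in \[0, 1\]), `summary` (scalar mean fraction over ocean),
#'   `n_time`, `lat`, `lon`, `land`.
#' @export
gap_fraction <- function(field, time_subset = NULL) {
  stopifnot(inherits(field, "gridded_field"))
  if (is.null(time_subset)) time_subset <- seq_along(field$time)
  if (length(time_subset) == 0) stop("`time_subset` must be nonempty")
  miss <- field$missing[time_subset, , , drop = FALSE]
  frac <- apply(miss, c(2, 3), mean)
  frac[field$land] <- NA_real_
  structure(
    list(fraction = frac, summary = mean(frac[!field$land]),
         n_time = length(time_subset), lat = field$lat, lon = field$lon,
         land = field$land),
    class = "gap_report"
  )
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> %.2f%% missing over %d ocean pixels, %d composites\n",
              100 * x$summary, sum(!x$land), x$n_time))
  invisible(x)
}
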