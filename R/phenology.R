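#' @name phenology
#' @title Bloom phenology by the threshold method
#' @description
#' Bloom initiation is declared at the first summer composite whose
#' chlorophyll exceeds a threshold of 5% above the annual median
#' (`threshold_factor = 1.05`); the bloom peak is the maximum chlorophyll
#' composite within the summer window (June-September by default).
#' Indices are computed per ensemble member on complete (gap-filled)
#' series, and the spread of dates across members is the uncertainty of
#' the timing caused by the missing data.
#'
#' The annual median is always taken over the whole year, but the
#' initiation scan is restricted by default to the summer months: in a
#' region with a secondary winter bloom, scanning from 1 January would
#' declare "initiation" on the decaying tail of the winter bloom (or on
#' any noise excursion 5% above the median) rather than on the summer
#' bloom the indicator targets. The scan window is configurable
#' (`init_months = 1:12` restores a whole-year scan).
NULL

#' Median of one year of composites
#'
#' @param series numeric vector of composite chlorophyll values for one
#'   year (complete after gap-filling).
#' @return The median (mg/m3); even-length series use the mean of the
#'   two middle values.
#' @export
annual_median <- function(series) {
  if (length(series) == 0 || all(is.na(series)))
    stop("annual_median() needs at least one valid composite")
  median(series, na.rm = TRUE)
}

#' Bloom initiation index
#'
#' First composite index within `search_window` whose value strictly
#' exceeds `threshold_factor` times the annual median of the whole
#' series. The window defaults to the whole series at this low level;
#' the higher-level wrappers ([bloom_indices()], [ensemble_phenology()])
#' default it to the summer months.
#'
#' @param series complete (gap-filled) composite series for one year.
#' @param threshold_factor multiplier on the annual median (default 1.05,
#'   i.e. 5% above).
#' @param search_window integer indices to scan, in increasing order
#'   (default: the whole series).
#' @return The initiation index, or `NA_integer_` if the threshold is
#'   never exceeded.
#' @export
bloom_initiation <- function(series, threshold_factor = 1.05,
                             search_window = seq_along(series)) {
  if (any(search_window < 1 | search_window > length(series)))
    stop("`search_window` is outside the year's composite range")
  thr <- threshold_factor * annual_median(series)
  hits <- search_window[which(series[search_window] > thr)]
  if (length(hits)) hits[1] else NA_integer_
}

#' Bloom peak index
#'
#' Index of the maximum chlorophyll composite within the summer window;
#' ties resolve to the earliest composite.
#'
#' @param series complete composite series for one year.
#' @param summer_window integer indices of the summer composites
#'   (nonempty).
#' @return The peak index.
#' @export
bloom_peak <- function(series, summer_window) {
  if (length(summer_window) == 0)
    stop("`summer_window` must be nonempty")
  if (any(summer_window < 1 | summer_window > length(series)))
    stop("`summer_window` is outside the year's composite range")
  summer_window[which.max(series[summer_window])]
}

#' Composite indices whose start date falls in given months
#'
#' @param dates composite start dates (class `Date`).
#' @param months integer months (default June-September).
#' @return Integer indices into `dates`.
#' @export
month_window <- function(dates, months = 6:9) {
  which(as.integer(format(as.Date(dates), "%m")) %in% months)
}

#' Bloom indices of a single complete series
#'
#' @param series complete composite series for one year.
#' @param dates composite start dates matching `series`.
#' @param threshold_factor multiplier on the annual median (default 1.05).
#' @param summer_months months defining the peak search window (default
#'   June-September).
#' @param init_months months scanned for initiation (default: the summer
#'   months; use `1:12` for a whole-year scan).
#' @return A list (`bloom_indices`): `initiation_index`, `peak_index`,
#'   `threshold_value`, and the corresponding dates.
#' @export
bloom_indices <- function(series, dates, threshold_factor = 1.05,
                          summer_months = 6:9, init_months = summer_months) {
  stopifnot(length(series) == length(dates))
  init <- bloom_initiation(series, threshold_factor,
                           month_window(dates, init_months))
  peak <- bloom_peak(series, month_window(dates, summer_months))
  list(initiation_index = init, peak_index = peak,
       threshold_value = threshold_factor * annual_median(series),
       initiation_date = if (is.na(init)) as.Date(NA) else as.Date(dates[init]),
       peak_date = as.Date(dates[peak]))
}

# Per-member series at a cell (i, j) or averaged over a region, for the
# composites of one calendar year. Returns list(series = matrix
# [n_composites x n_members], dates).
member_series <- function(ens, year, cell = NULL, region = NULL) {
  base <- ens$base_field
  t_idx <- which(as.integer(format(base$time, "%Y")) == year)
  if (!length(t_idx)) stop("no composites for year ", year)
  if (is.null(cell) && is.null(region))
    stop("give either `cell` (lat index, lon index) or `region`")
  if (!is.null(cell)) {
    ii <- cell[1]; jj <- cell[2]
    if (base$land[ii, jj]) stop("cell is land")
    sel <- cbind(ii, jj)
  } else {
    sel <- as.matrix(expand.grid(i = region$lat_idx, j = region$lon_idx))
    sel <- sel[!base$land[sel], , drop = FALSE]
    if (!nrow(sel)) stop("region contains no ocean pixels")
  }
  n_t <- length(t_idx)
  series <- matrix(0, n_t, ens$n_members)
  draws <- if (length(ens$imputed_idx)) imputed_draws(ens) else NULL
  d <- dim(base$values)
  for (r in seq_len(nrow(sel))) {
    flat <- t_idx + d[1] * ((sel[r, 1] - 1) + d[2] * (sel[r, 2] - 1))
    col <- base$values[flat]                       # shared across members
    contrib <- matrix(col, n_t, ens$n_members)
    imp <- match(flat, ens$imputed_idx)
    hit <- which(!is.na(imp))
    if (length(hit)) contrib[hit, ] <- draws[imp[hit], , drop = FALSE]
    series <- series + contrib
  }
  list(series = series / nrow(sel), dates = base$time[t_idx])
}

#' Ensemble bloom phenology with uncertainty range
#'
#' Computes the bloom initiation and peak for every ensemble member at a
#' grid cell (or averaged over a region) for one calendar year, and
#' summarises the spread of dates: the `[min, max]` range is the
#' uncertainty of the timing due to gap-filling, and the mean date (over
#' members with a detected event, rounded to the nearest composite) is
#' the central estimate.
#'
#' @param ens an `ensemble_set` whose members are complete for `year`.
#' @param year calendar year to score.
#' @param cell integer pair `(lat index, lon index)`.
#' @param region alternatively, `list(lat_idx =, lon_idx =)`; the member
#'   series is the mean over the region's ocean pixels.
#' @param threshold_factor,summer_months,init_months as in
#'   [bloom_indices()].
#' @return An object of class `phenology_summary`: per-member indices,
#'   min/mean/max initiation and peak (indices and dates), and the
#'   fraction of members with no detected initiation.
#' @export
ensemble_phenology <- function(ens, year, cell = NULL, region = NULL,
                               threshold_factor = 1.05, summer_months = 6:9,
                               init_months = summer_months) {
  stopifnot(inherits(ens, "ensemble_set"))
  ms <- member_series(ens, year, cell = cell, region = region)
  if (anyNA(ms$series))
    stop("ensemble members are not complete for year ", year)
  search_window <- month_window(ms$dates, init_months)
  summer <- month_window(ms$dates, summer_months)
  n_m <- ens$n_members
  init <- integer(n_m); peak <- integer(n_m)
  for (m in seq_len(n_m)) {
    init[m] <- bloom_initiation(ms$series[, m], threshold_factor, search_window)
    peak[m] <- bloom_peak(ms$series[, m], summer)
  }
  detected <- !is.na(init)
  summarise <- function(idx) {
    if (!length(idx)) return(list(min = NA, mean = NA, max = NA))
    list(min = min(idx), mean = as.integer(round(mean(idx))), max = max(idx))
  }
  si <- summarise(init[detected])
  sp <- summarise(peak)
  to_date <- function(i) if (is.na(i)) as.Date(NA) else as.Date(ms$dates[i])
  structure(
    list(year = year, dates = ms$dates,
         members = data.frame(member = seq_len(n_m), initiation_index = init,
                              peak_index = peak),
         initiation = list(min = si$min, mean = si$mean, max = si$max,
                           min_date = to_date(si$min), mean_date = to_date(si$mean),
                           max_date = to_date(si$max)),
         peak = list(min = sp$min, mean = sp$mean, max = sp$max,
                     min_date = to_date(sp$min), mean_date = to_date(sp$mean),
                     max_date = to_date(sp$max)),
         frac_undetected = mean(!detected),
         threshold_factor = threshold_factor),
    class = "phenology_summary")
}

#' @export
print.phenology_summary <- function(x, ...) {
  fd <- function(d) if (is.na(d)) "none" else format(d, "%d %b")
  cat(sprintf("<phenology_summary> year %d (%d members)\n",
              x$year, nrow(x$members)))
  if (all(is.na(x$members$initiation_index))) {
    cat("  initiation: not detected in any member\n")
  } else {
    cat(sprintf("  initiation: %s .. %s (mean %s; undetected in %.0f%% of members)\n",
                fd(x$initiation$min_date), fd(x$initiation$max_date),
                fd(x$initiation$mean_date), 100 * x$frac_undetected))
  }
  cat(sprintf("  peak:       %s .. %s (mean %s)\n",
              fd(x$peak$min_date), fd(x$peak$max_date), fd(x$peak$mean_date)))
  invisible(x)
}
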