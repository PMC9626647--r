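#' @name io
#' @title CF-style netCDF and tabular input/output
#' @description
#' Gridded fields travel as CF-style netCDF: variable `chlor_a`
#' (mg m-3) over dimensions (time, lat, lon), missing observations as
#' the fill value, land as an auxiliary byte variable `land_mask`.
#' Gap reports are written as CSV (one ocean pixel per row) plus a JSON
#' summary; per-cell fit tables and phenology results as CSV.
NULL

#' Write a gridded field to netCDF
#'
#' @param field a [gridded_field].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chl_nc <- function(field, path) {
  stopifnot(inherits(field, "gridded_field"))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  dim_time <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                               as.numeric(field$time), unlim = TRUE)
  fillv <- 9.96921e36
  var_chl <- ncdf4::ncvar_def("chlor_a", "mg m-3",
                              list(dim_lon, dim_lat, dim_time), fillv,
                              longname = "surface chlorophyll-a concentration",
                              prec = "double")
  var_land <- ncdf4::ncvar_def("land_mask", "1", list(dim_lon, dim_lat),
                               missval = NULL, prec = "byte",
                               longname = "1 = land, never filled")
  nc <- ncdf4::nc_create(path, list(var_chl, var_land))
  on.exit(ncdf4::nc_close(nc))
  # internal layout is (time, lat, lon); netCDF wants (lon, lat, time)
  ncdf4::ncvar_put(nc, var_chl, aperm(field$values, c(3, 2, 1)))
  ncdf4::ncvar_put(nc, var_land, t(field$land) * 1L)
  invisible(path)
}

#' Read a gridded field from netCDF
#'
#' Expects the layout written by [write_chl_nc()]: `chlor_a` on
#' (lon, lat, time) with missing as fill value or NaN, and an optional
#' `land_mask` byte variable.
#'
#' @param path netCDF file path.
#' @return A [gridded_field].
#' @export
read_chl_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  vals <- ncdf4::ncvar_get(nc, "chlor_a", collapse_degen = FALSE)
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  time <- as.Date(as.numeric(ncdf4::ncvar_get(nc, "time")),
                  origin = "1970-01-01")
  land <- if ("land_mask" %in% names(nc$var)) {
    t(matrix(ncdf4::ncvar_get(nc, "land_mask") != 0,
             length(lon), length(lat)))
  } else NULL
  vals[is.nan(vals)] <- NA_real_
  gridded_field(aperm(vals, c(3, 2, 1)), time, lat, lon, land = land)
}

#' Write ensemble members to netCDF
#'
#' Either a single file with an `ensemble` dimension (`mode =
#' "single"`), or one file per member under a directory (`mode =
#' "per_member"`). Members are materialized on demand from the master
#' seed, so any subset can be written without holding the whole ensemble
#' in memory.
#'
#' @param ens an `ensemble_set`.
#' @param path output file (single mode) or directory (per-member mode).
#' @param members integer vector of member indices (default: all).
#' @param mode `"single"` or `"per_member"`.
#' @return `path`, invisibly.
#' @export
write_ensemble_nc <- function(ens, path, members = seq_len(ens$n_members),
                              mode = c("single", "per_member")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ens, "ensemble_set"))
  base <- ens$base_field
  if (mode == "per_member") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in members)
      write_chl_nc(ensemble_member(ens, k),
                   file.path(path, sprintf("member_%05d.nc", k)))
    return(invisible(path))
  }
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", base$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", base$lat)
  dim_time <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                               as.numeric(base$time))
  dim_ens <- ncdf4::ncdim_def("ensemble", "1", members)
  fillv <- 9.96921e36
  var_chl <- ncdf4::ncvar_def("chlor_a", "mg m-3",
                              list(dim_lon, dim_lat, dim_time, dim_ens),
                              fillv, prec = "double")
  nc <- ncdf4::nc_create(path, var_chl)
  on.exit(ncdf4::nc_close(nc))
  for (s in seq_along(members)) {
    mem <- ensemble_member(ens, members[s])
    ncdf4::ncvar_put(nc, var_chl, aperm(mem$values, c(3, 2, 1)),
                     start = c(1, 1, 1, s),
                     count = c(length(base$lon), length(base$lat),
                               length(base$time), 1))
  }
  invisible(path)
}

#' Write ensemble summary statistics to netCDF
#'
#' Stores the pointwise ensemble mean and 25th/75th percentile bands
#' from [ensemble_summary()].
#'
#' @param summ result of [ensemble_summary()].
#' @param base the base [gridded_field] (for coordinates).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_nc <- function(summ, base, path) {
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", base$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", base$lat)
  dim_time <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                               as.numeric(base$time))
  fillv <- 9.96921e36
  dims <- list(dim_lon, dim_lat, dim_time)
  vars <- list(
    ncdf4::ncvar_def("chlor_a_mean", "mg m-3", dims, fillv, prec = "double"),
    ncdf4::ncvar_def("chlor_a_p25", "mg m-3", dims, fillv, prec = "double"),
    ncdf4::ncvar_def("chlor_a_p75", "mg m-3", dims, fillv, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vars[[1]], aperm(summ$mean, c(3, 2, 1)))
  ncdf4::ncvar_put(nc, vars[[2]], aperm(summ$p25, c(3, 2, 1)))
  ncdf4::ncvar_put(nc, vars[[3]], aperm(summ$p75, c(3, 2, 1)))
  invisible(path)
}

#' Write a gap report as CSV + JSON
#'
#' @param report a `gap_report` from [gap_fraction()].
#' @param csv_path per-pixel CSV (columns lat, lon, missing_fraction;
#'   ocean pixels only).
#' @param json_path JSON summary (`percent_missing`, `n_time`,
#'   `n_ocean_pixels`).
#' @return A list with the two paths, invisibly.
#' @export
write_gap_report <- function(report, csv_path, json_path = NULL) {
  stopifnot(inherits(report, "gap_report"))
  grid <- expand.grid(lat = report$lat, lon = report$lon)
  df <- data.frame(lat = grid$lat, lon = grid$lon,
                   missing_fraction = as.vector(report$fraction))
  df <- df[!as.vector(report$land), ]
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(percent_missing = 100 * report$summary,
           n_time = report$n_time, n_ocean_pixels = sum(!report$land)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv_path, json = json_path))
}

#' Write ensemble phenology results as CSV
#'
#' One row per member (ISO-8601 dates) plus a one-row summary file with
#' the min/mean/max dates and the undetected fraction.
#'
#' @param summary a `phenology_summary`.
#' @param members_path CSV path for per-member indices and dates.
#' @param summary_path CSV path for the min/mean/max summary.
#' @return Paths, invisibly.
#' @export
write_phenology_csv <- function(summary, members_path, summary_path = NULL) {
  stopifnot(inherits(summary, "phenology_summary"))
  df <- summary$members
  df$year <- summary$year
  df$initiation_date <- format(summary$dates[df$initiation_index], "%Y-%m-%d")
  df$peak_date <- format(summary$dates[df$peak_index], "%Y-%m-%d")
  utils::write.csv(df, members_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- data.frame(
      year = summary$year,
      initiation_min = format(summary$initiation$min_date, "%Y-%m-%d"),
      initiation_mean = format(summary$initiation$mean_date, "%Y-%m-%d"),
      initiation_max = format(summary$initiation$max_date, "%Y-%m-%d"),
      peak_min = format(summary$peak$min_date, "%Y-%m-%d"),
      peak_mean = format(summary$peak$mean_date, "%Y-%m-%d"),
      peak_max = format(summary$peak$max_date, "%Y-%m-%d"),
      frac_undetected = summary$frac_undetected)
    utils::write.csv(s, summary_path, row.names = FALSE)
  }
  invisible(list(members = members_path, summary = summary_path))
}
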