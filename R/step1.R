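#' @name step1
#' @title Step I: optimal linear interpolation
#' @description
#' The first step of the gap-filling algorithm replaces a missing ocean
#' pixel by the equally weighted arithmetic mean of its two immediate
#' neighbours along one axis. An invalid neighbour (land, missing, or
#' domain edge) receives zero weight, so a single valid neighbour fills
#' the gap by itself; when both neighbours are invalid the gap is left
#' unfilled. The stencil is deliberately restricted to the immediate
#' neighbours: averaging over a wider neighbourhood blends sub-grid
#' patchiness of the bloom field and biases the reconstruction.
NULL

# Neighbour-mean estimate along one axis, computed from the current state
# of `values`. Returns an array of the same shape: the two-neighbour mean
# where at least one neighbour is valid, NA elsewhere. No wrap-around.
axis_estimates <- function(values, axis = c("lon", "lat", "time")) {
  axis <- match.arg(axis)
  dimno <- switch(axis, time = 1L, lat = 2L, lon = 3L)
  d <- dim(values)
  n <- d[dimno]
  shift <- function(by) {
    idx <- seq_len(n) + by
    idx[idx < 1L | idx > n] <- NA
    switch(dimno,
           values[idx, , , drop = FALSE],
           values[, idx, , drop = FALSE],
           values[, , idx, drop = FALSE])
  }
  prev <- shift(-1L); nxt <- shift(1L)
  vp <- !is.na(prev); vn <- !is.na(nxt)
  p0 <- prev; p0[!vp] <- 0
  n0 <- nxt;  n0[!vn] <- 0
  cnt <- vp + vn
  est <- (p0 + n0) / cnt
  est[cnt == 0L] <- NA_real_
  list(est = est, n_neighbours = cnt)
}

#' Single interpolation pass along one axis
#'
#' Fills missing ocean pixels from the mean of their two immediate
#' neighbours along `axis`. All fills in a pass are computed
#' simultaneously from the pre-pass state, so the result is independent
#' of scan order and newly filled values never seed further fills within
#' the same pass. Observed pixels are never modified.
#'
#' @param field a [gridded_field].
#' @param axis one of `"lon"`, `"lat"`, `"time"`.
#' @return A [gridded_field] with (weakly) fewer missing pixels.
#' @export
fill_axis_pass <- function(field, axis = c("lon", "lat", "time")) {
  axis <- match.arg(axis)
  stopifnot(inherits(field, "gridded_field"))
  est <- axis_estimates(field$values, axis)$est
  fillable <- field$missing & !is.na(est)
  field$values[fillable] <- est[fillable]
  field$missing <- field$missing & !fillable
  field
}

#' Step I: sequential optimal interpolation (lon, then lat, then time)
#'
#' Applies [fill_axis_pass()] along longitude, latitude and time in that
#' order, each pass operating on the output of the previous one. The
#' ordering follows the variability of the bloom field: zonal variation
#' is weakest, meridional stronger, and week-to-week temporal variation
#' strongest, so the axes are used in increasing order of expected
#' interpolation error (see [pass_rmse()]).
#'
#' @param field a [gridded_field].
#' @return A [gridded_field]; the set of missing pixels shrinks (weakly)
#'   at every pass, and observed values are bit-identical to the input.
#' @export
optimal_interpolate <- function(field) {
  field <- fill_axis_pass(field, "lon")
  field <- fill_axis_pass(field, "lat")
  fill_axis_pass(field, "time")
}

#' Holdout RMSE of one-axis interpolation
#'
#' Cross-validates the two-neighbour averaging rule along a single axis:
#' a random fraction of observed pixels is withheld (seeded), the rule is
#' applied to the degraded field, and the root-mean-square error over the
#' predictable held-out pixels is returned. Comparing axes ranks them by
#' interpolation skill and justifies the lon - lat - time pass order.
#'
#' @param field a [gridded_field].
#' @param axis one of `"lon"`, `"lat"`, `"time"`.
#' @param holdout_fraction fraction of observed pixels to withhold
#'   (default 0.1).
#' @param seed integer seed for the holdout draw.
#' @return RMSE in mg/m3 over held-out pixels that retained both
#'   neighbours (the two-point rule is only unbiased there; one-sided
#'   boundary predictions are excluded from scoring).
#' @export
pass_rmse <- function(field, axis = c("lon", "lat", "time"),
                      holdout_fraction = 0.1, seed = 1L) {
  axis <- match.arg(axis)
  stopifnot(inherits(field, "gridded_field"),
            holdout_fraction > 0, holdout_fraction < 1)
  obs_idx <- which(!is.na(field$values))
  n_hold <- max(1L, floor(holdout_fraction * length(obs_idx)))
  hold <- with_seed(seed, sample(obs_idx, n_hold))
  degraded <- field$values
  degraded[hold] <- NA_real_
  est <- axis_estimates(degraded, axis)
  pred <- est$est[hold]
  usable <- est$n_neighbours[hold] == 2L
  if (!any(usable))
    stop("no held-out pixel has both neighbours valid along this axis")
  truth <- field$values[hold]
  sqrt(mean((pred[usable] - truth[usable])^2))
}
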