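#' @name montecarlo
#' @title Step II: Monte-Carlo multiple imputation
#' @description
#' Every ocean pixel still missing after Step I is filled with N
#' pseudo-random draws from its grid cell's best-fit distribution,
#' yielding an ensemble of N complete fields that agree exactly at every
#' observed or interpolated pixel and differ only at imputed pixels. The
#' spread of any statistic across the ensemble quantifies the
#' uncertainty caused by the missing data. Draws are independent across
#' pixels and across members: the per-grid marginal distributions carry
#' no spatial or temporal correlation (a deliberate limitation; see the
#' package vignette).
NULL

#' Draw positive pseudo-random values from a fitted distribution
#'
#' Chlorophyll concentration is strictly positive, but a fitted normal or
#' a KDE can place probability mass below zero. Non-positive draws are
#' rejected and redrawn (up to 1000 rounds); any survivors are clipped to
#' the cell's minimum observed value.
#'
#' @param fitted a `fitted_distribution`.
#' @param n number of draws (>= 1).
#' @param seed integer seed; draws are reproducible given `(fitted, n,
#'   seed)`.
#' @return Numeric vector of `n` strictly positive values.
#' @export
draw_values <- function(fitted, n, seed = 1L) {
  stopifnot(inherits(fitted, "fitted_distribution"), n >= 1)
  raw_draw <- function(m) {
    switch(fitted$family,
      normal = rnorm(m, fitted$location, fitted$scale),
      lognormal = fitted$location + rlnorm(m, log(fitted$scale), fitted$shape),
      gamma = fitted$location +
        rgamma(m, shape = fitted$shape, scale = fitted$scale),
      kde = sample(fitted$kde$training_sample, m, replace = TRUE) +
        rnorm(m, 0, fitted$kde$bandwidth))
  }
  with_seed(seed, {
    x <- raw_draw(n)
    for (round in seq_len(1000L)) {
      bad <- which(x <= 0)
      if (!length(bad)) break
      x[bad] <- raw_draw(length(bad))
    }
    x[x <= 0] <- max(fitted$sample_min, .Machine$double.eps)
    x
  })
}

#' Generate the gap-filled ensemble
#'
#' Builds an `ensemble_set`: N members that all equal the Step-I output
#' `base` wherever it is observed or interpolated, with each remaining
#' missing ocean pixel filled independently per member from its cell's
#' fitted distribution. Each pixel owns a private random substream
#' derived from `(seed, time, lat, lon)`, so the result is independent of
#' pixel traversal order and members can be regenerated lazily from the
#' master seed. Missing pixels in cells without a fit (fewer than 8
#' observations) are flagged `unfilled` and excluded from the gap-free
#' guarantee.
#'
#' @param base a [gridded_field], normally the Step-I output.
#' @param fits per-cell fit list from [fit_field()] (its `fits` element).
#' @param n_members ensemble size N (default 10000).
#' @param seed master seed.
#' @param materialize if `TRUE`, draw and cache the full imputation
#'   matrix now; otherwise it is generated on first use.
#' @return An object of class `ensemble_set`.
#' @export
generate_ensembles <- function(base, fits, n_members = 10000L, seed = 1L,
                               materialize = FALSE) {
  stopifnot(inherits(base, "gridded_field"), n_members >= 1)
  d <- dim(base$values)
  miss_idx <- which(base$missing)
  coord <- arrayInd(miss_idx, d)
  keys <- if (length(miss_idx)) paste0(coord[, 2], "_", coord[, 3]) else character(0)
  has_fit <- vapply(keys, function(k) !is.null(fits[[k]]), logical(1),
                    USE.NAMES = FALSE)
  unfilled <- miss_idx[!has_fit]
  if (length(unfilled))
    message(sprintf("[WARN] %d missing pixels lie in cells without a fitted PDF and stay unfilled",
                    length(unfilled)))
  imputed <- miss_idx[has_fit]
  coord <- coord[has_fit, , drop = FALSE]
  pixel_seeds <- if (nrow(coord)) vapply(seq_len(nrow(coord)), function(r)
    substream_seed(seed, coord[r, 1], coord[r, 2], coord[r, 3]),
    integer(1)) else integer(0)
  ens <- structure(
    list(base_field = base, fits = fits, n_members = as.integer(n_members),
         seed = as.integer(seed), imputed_idx = imputed,
         imputed_coord = coord, imputed_keys = keys[has_fit],
         pixel_seeds = pixel_seeds, unfilled_idx = unfilled,
         draw_cache = new.env(parent = emptyenv())),
    class = "ensemble_set")
  if (materialize) imputed_draws(ens)
  ens
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf("<ensemble_set> %d members, %d imputed pixels (%d unfillable)\n",
              x$n_members, length(x$imputed_idx), length(x$unfilled_idx)))
  invisible(x)
}

#' Imputation matrix of an ensemble
#'
#' The full matrix of Monte-Carlo draws: one row per imputed pixel, one
#' column per ensemble member. Generated deterministically from the
#' per-pixel substreams and cached inside the object.
#'
#' @param ens an `ensemble_set`.
#' @return Numeric matrix `length(ens$imputed_idx)` x `ens$n_members`.
#' @export
imputed_draws <- function(ens) {
  stopifnot(inherits(ens, "ensemble_set"))
  if (!is.null(ens$draw_cache$draws)) return(ens$draw_cache$draws)
  n_pix <- length(ens$imputed_idx)
  draws <- matrix(NA_real_, n_pix, ens$n_members)
  for (r in seq_len(n_pix)) {
    fit <- ens$fits[[ens$imputed_keys[r]]]
    draws[r, ] <- draw_values(fit, ens$n_members, seed = ens$pixel_seeds[r])
  }
  ens$draw_cache$draws <- draws
  draws
}

#' Materialize one ensemble member
#'
#' @param ens an `ensemble_set`.
#' @param k member index in `1:n_members`.
#' @return A gap-free [gridded_field] equal to the base field except at
#'   imputed pixels, which hold member `k`'s draws.
#' @export
ensemble_member <- function(ens, k) {
  stopifnot(inherits(ens, "ensemble_set"), k >= 1, k <= ens$n_members)
  field <- ens$base_field
  if (length(ens$imputed_idx)) {
    draws <- imputed_draws(ens)
    field$values[ens$imputed_idx] <- draws[, k]
    field$missing[ens$imputed_idx] <- FALSE
  }
  field
}

#' Pointwise ensemble statistics
#'
#' Per-pixel mean, 25th/75th percentile band, and outlier count across
#' members (a member value is an outlier when it falls outside the
#' whiskers at 1.5 interquartile ranges beyond the quartiles, the usual
#' boxplot convention). At non-imputed pixels all members agree, so the
#' band width is exactly zero.
#'
#' @param ens an `ensemble_set` with at least 4 members.
#' @return List of three arrays shaped like the field (`mean`, `p25`,
#'   `p75`) plus `n_outliers` (same shape, zero at non-imputed pixels).
#' @export
ensemble_summary <- function(ens) {
  stopifnot(inherits(ens, "ensemble_set"))
  if (ens$n_members < 4)
    stop("ensemble_summary() needs at least 4 members")
  base <- ens$base_field$values
  out <- list(mean = base, p25 = base, p75 = base,
              n_outliers = array(0L, dim(base)))
  if (length(ens$imputed_idx)) {
    draws <- imputed_draws(ens)
    q <- apply(draws, 1, quantile, probs = c(0.25, 0.75), names = FALSE,
               type = 7)
    iqr <- q[2, ] - q[1, ]
    out$mean[ens$imputed_idx] <- rowMeans(draws)
    out$p25[ens$imputed_idx] <- q[1, ]
    out$p75[ens$imputed_idx] <- q[2, ]
    out$n_outliers[ens$imputed_idx] <- rowSums(
      draws < q[1, ] - 1.5 * iqr | draws > q[2, ] + 1.5 * iqr)
  }
  out
}
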