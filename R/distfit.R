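#' @name distfit
#' @title Per-grid-cell best-fit probability distributions
#' @description
#' Step II imputes each remaining gap from the probability distribution
#' of the chlorophyll values observed at that grid cell, pooled over the
#' full time axis. Three parametric candidates (normal, lognormal, gamma)
#' are fitted by maximum likelihood; a one-sample Kolmogorov-Smirnov test
#' scores each, and the candidate with the largest p-value is selected
#' provided that p >= 0.05. When every parametric candidate is rejected
#' the cell falls back to a Gaussian-kernel density estimate whose
#' bandwidth is chosen by cross-validation, which captures multimodal
#' cells that no single parametric family represents.
#'
#' Parameters follow the shape/location/scale convention: the lognormal
#' and gamma carry a shape, a scale and a lower-bound location shift; the
#' normal carries location (mean) and scale (standard deviation).
#' Chlorophyll is positive, so the location shift is constrained to be
#' non-negative and below the sample minimum.
NULL

new_fitted_distribution <- function(family, shape = NA_real_, location = NA_real_,
                                    scale = NA_real_, ks_pvalue = NA_real_,
                                    ks_pvalues = NULL, kde = NULL,
                                    sample_size = NA_integer_,
                                    sample_min = NA_real_, loglik = NA_real_) {
  structure(
    list(family = family, shape = shape, location = location, scale = scale,
         ks_pvalue = ks_pvalue, ks_pvalues = ks_pvalues, kde = kde,
         sample_size = sample_size, sample_min = sample_min, loglik = loglik),
    class = "fitted_distribution"
  )
}

#' @export
print.fitted_distribution <- function(x, ...) {
  if (x$family == "kde") {
    cat(sprintf("<fitted_distribution> kde (Gaussian kernel, bandwidth %.4g, n = %d)\n",
                x$kde$bandwidth, x$sample_size))
  } else {
    cat(sprintf("<fitted_distribution> %s shape=%.4g location=%.4g scale=%.4g (K-S p = %.3g, n = %d)\n",
                x$family, x$shape, x$location, x$scale, x$ks_pvalue, x$sample_size))
  }
  invisible(x)
}

MIN_FIT_SAMPLE <- 8L

check_fit_sample <- function(sample) {
  if (length(sample) < MIN_FIT_SAMPLE)
    stop(sprintf("need at least %d values to fit a distribution (got %d)",
                 MIN_FIT_SAMPLE, length(sample)))
  if (any(!is.finite(sample)) || any(sample <= 0))
    stop("sample must contain only finite, strictly positive values")
}

# --- shifted-family maximum likelihood -------------------------------------

# For a fixed location shift the inner MLEs are closed-form (lognormal,
# normal) or a two-step Newton iteration on the shape (gamma); the shift
# itself is then chosen by profile likelihood on [0, 0.95 * min(sample)].
# The 0.95 margin keeps the optimiser away from the likelihood singularity
# that shifted lognormal/gamma models exhibit as the shift approaches the
# sample minimum.

fit_lnorm_at <- function(x, loc) {
  y <- log(x - loc)
  mu <- mean(y); sg <- pop_sd(y)
  if (sg <= 0) sg <- .Machine$double.eps
  list(shape = sg, location = loc, scale = exp(mu),
       loglik = sum(dlnorm(x - loc, mu, sg, log = TRUE)))
}

gamma_shape_mle <- function(y) {
  s <- log(mean(y)) - mean(log(y))
  if (s <= 0) return(Inf)
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:8) {
    step <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    k <- k - step
    if (!is.finite(k) || k <= 0) return(Inf)
    if (abs(step) < 1e-10 * k) break
  }
  k
}

fit_gamma_at <- function(x, loc) {
  y <- x - loc
  k <- gamma_shape_mle(y)
  if (!is.finite(k)) {           # zero-variance sample: degenerate limit
    k <- 1e8
  }
  sc <- mean(y) / k
  list(shape = k, location = loc, scale = sc,
       loglik = sum(dgamma(y, shape = k, scale = sc, log = TRUE)))
}

profile_location_fit <- function(x, fit_at) {
  f0 <- fit_at(x, 0)
  hi <- 0.95 * min(x)
  if (hi <= 0 || !is.finite(f0$loglik)) return(f0)
  opt <- tryCatch(
    stats::optimize(function(l) fit_at(x, l)$loglik, c(0, hi), maximum = TRUE),
    error = function(e) NULL)
  if (is.null(opt)) return(f0)
  f1 <- fit_at(x, opt$maximum)
  if (is.finite(f1$loglik) && f1$loglik > f0$loglik) f1 else f0
}

#' Maximum-likelihood fit of one parametric family
#'
#' @param sample numeric vector of strictly positive values, length >= 8.
#' @param family `"normal"`, `"lognormal"` or `"gamma"`.
#' @return A `fitted_distribution`. Normal: location = sample mean,
#'   scale = population standard deviation. Lognormal/gamma: shape and
#'   scale of the shifted family with the location shift estimated by
#'   profile likelihood over \[0, 0.95 min(sample)\].
#' @export
fit_family <- function(sample, family = c("normal", "lognormal", "gamma")) {
  family <- match.arg(family)
  check_fit_sample(sample)
  fit <- switch(family,
    normal = {
      sg <- pop_sd(sample)
      if (sg <= 0) sg <- .Machine$double.eps
      list(shape = NA_real_, location = mean(sample), scale = sg,
           loglik = sum(dnorm(sample, mean(sample), sg, log = TRUE)))
    },
    lognormal = profile_location_fit(sample, fit_lnorm_at),
    gamma = profile_location_fit(sample, fit_gamma_at))
  new_fitted_distribution(family,
                          shape = fit$shape, location = fit$location,
                          scale = fit$scale, sample_size = length(sample),
                          sample_min = min(sample), loglik = fit$loglik)
}

#' Cumulative distribution function of a parametric fit
#'
#' @param fitted a parametric `fitted_distribution`.
#' @return A vectorised function q -> P(X <= q).
#' @export
fitted_cdf <- function(fitted) {
  stopifnot(inherits(fitted, "fitted_distribution"))
  switch(fitted$family,
    normal = function(q) pnorm(q, fitted$location, fitted$scale),
    lognormal = function(q) plnorm(q - fitted$location,
                                   log(fitted$scale), fitted$shape),
    gamma = function(q) pgamma(q - fitted$location,
                               shape = fitted$shape, scale = fitted$scale),
    stop("no closed-form CDF for family '", fitted$family, "'"))
}

#' One-sample Kolmogorov-Smirnov test against a parametric fit
#'
#' Standard one-sample K-S statistic sup |F_n - F| with its asymptotic
#' p-value. The parameters of `fitted` were estimated from the same
#' sample, which makes the standard p-value anticonservative; the test is
#' used as a relative goodness-of-fit score for candidate selection, not
#' as a calibrated hypothesis test.
#'
#' @param sample the data the fit was computed from.
#' @param fitted a parametric `fitted_distribution` (KDE fits are not
#'   scored by K-S).
#' @return list with `statistic` and `p_value`.
#' @export
ks_test <- function(sample, fitted) {
  stopifnot(inherits(fitted, "fitted_distribution"))
  if (fitted$family == "kde")
    stop("K-S selection applies to parametric candidates only")
  ht <- suppressWarnings(stats::ks.test(sample, fitted_cdf(fitted)))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

# --- kernel density estimation ---------------------------------------------

# mean held-out log-density of points x0 under a Gaussian KDE built on train
kde_heldout_score <- function(train, x0, bw) {
  dens <- vapply(x0, function(p) mean(dnorm(p - train, sd = bw)), numeric(1))
  mean(log(pmax(dens, 1e-300)))
}

#' Gaussian KDE with cross-validated bandwidth
#'
#' Fits a Gaussian-kernel density estimate to a cell's values, selecting
#' the bandwidth that maximises the mean held-out log-density over k-fold
#' cross-validation. Candidates are `n_bandwidths` log-spaced values
#' spanning 0.1x to 10x the Silverman rule-of-thumb bandwidth. The fold
#' assignment is seeded, so the fit is deterministic given the sample.
#'
#' A zero-variance sample has no defined CV optimum; it falls back to the
#' bandwidth `max(1e-6, 1e-3 |c|)` around the constant `c`, so imputation
#' returns (essentially) that constant.
#'
#' @param sample numeric vector, length >= 8.
#' @param n_folds folds for cross-validation (default 5).
#' @param n_bandwidths size of the candidate grid (default 20).
#' @param fold_seed seed for the fold shuffle (default 1).
#' @return A `fitted_distribution` with `family = "kde"`; its `kde`
#'   element holds `training_sample` and `bandwidth`.
#' @export
fit_kde_cv <- function(sample, n_folds = 5L, n_bandwidths = 20L, fold_seed = 1L) {
  check_fit_sample(sample)
  n <- length(sample)
  if (pop_sd(sample) == 0) {
    bw <- max(1e-6, 1e-3 * abs(sample[1]))
  } else {
    bw0 <- stats::bw.nrd0(sample)
    grid <- exp(seq(log(0.1 * bw0), log(10 * bw0), length.out = n_bandwidths))
    folds <- with_seed(fold_seed, sample(rep_len(seq_len(n_folds), n)))
    scores <- vapply(grid, function(h) {
      mean(vapply(seq_len(n_folds), function(f) {
        kde_heldout_score(sample[folds != f], sample[folds == f], h)
      }, numeric(1)))
    }, numeric(1))
    bw <- grid[which.max(scores)]
  }
  new_fitted_distribution("kde",
                          kde = list(kernel = "gaussian", bandwidth = bw,
                                     training_sample = sample),
                          sample_size = n, sample_min = min(sample))
}

#' Density of a KDE fit
#'
#' @param fitted a `fitted_distribution` with `family = "kde"`.
#' @return A vectorised density function.
#' @export
kde_density <- function(fitted) {
  stopifnot(inherits(fitted, "fitted_distribution"), fitted$family == "kde")
  train <- fitted$kde$training_sample
  bw <- fitted$kde$bandwidth
  function(x) vapply(x, function(p) mean(dnorm(p - train, sd = bw)), numeric(1))
}

#' Select the best-fit PDF for a cell
#'
#' Fits all three parametric families, scores each by the one-sample K-S
#' test, and returns the family with the largest p-value when that
#' p-value is at least 0.05; otherwise every parametric candidate is
#' considered a poor fit and the Gaussian KDE fallback is returned. All
#' candidate p-values are recorded on the returned object (`ks_pvalues`)
#' for reporting.
#'
#' @param sample numeric vector of positive values, length >= 8.
#' @param p_threshold rejection threshold for the parametric candidates
#'   (default 0.05).
#' @param fold_seed seed forwarded to [fit_kde_cv()] when the fallback is
#'   taken.
#' @return A `fitted_distribution`.
#' @export
select_pdf <- function(sample, p_threshold = 0.05, fold_seed = 1L) {
  check_fit_sample(sample)
  fams <- c("normal", "lognormal", "gamma")
  fits <- lapply(fams, function(f) fit_family(sample, f))
  pvals <- vapply(fits, function(f) ks_test(sample, f)$p_value, numeric(1))
  names(pvals) <- fams
  if (max(pvals) >= p_threshold) {
    best <- fits[[which.max(pvals)]]
    best$ks_pvalue <- max(pvals)
    best$ks_pvalues <- pvals
    best
  } else {
    kde <- fit_kde_cv(sample, fold_seed = fold_seed)
    kde$ks_pvalues <- pvals
    kde
  }
}

# --- per-field fitting ------------------------------------------------------

#' Fit a best-fit PDF at every ocean grid cell
#'
#' Pools each cell's valid values over the whole time axis (all seasons,
#' all years) and runs [select_pdf()]. Cells with fewer than 8 valid
#' values cannot be fitted; they are reported with family `"unfit"` and
#' are left to Step I alone.
#'
#' @param field a [gridded_field] (typically the Step-I output).
#' @param p_threshold,fold_seed forwarded to [select_pdf()].
#' @return A list with `fits` (list indexed by cell key `"i_j"`) and
#'   `table` (one data.frame row per ocean cell: lat, lon, family,
#'   shape, location, scale, bandwidth, the three candidate K-S p-values,
#'   sample_size).
#' @export
fit_field <- function(field, p_threshold = 0.05, fold_seed = 1L) {
  stopifnot(inherits(field, "gridded_field"))
  d <- dim(field$values)
  fits <- list()
  rows <- list()
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    if (field$land[i, j]) next
    vals <- field$values[, i, j]
    vals <- vals[!is.na(vals)]
    key <- paste0(i, "_", j)
    if (length(vals) < MIN_FIT_SAMPLE) {
      fits[[key]] <- NULL
      rows[[key]] <- data.frame(lat = field$lat[i], lon = field$lon[j],
                                family = "unfit", shape = NA, location = NA,
                                scale = NA, bandwidth = NA,
                                p_normal = NA, p_lognormal = NA, p_gamma = NA,
                                sample_size = length(vals))
      next
    }
    f <- select_pdf(vals, p_threshold = p_threshold,
                    fold_seed = substream_seed(fold_seed, i, j))
    fits[[key]] <- f
    rows[[key]] <- data.frame(
      lat = field$lat[i], lon = field$lon[j], family = f$family,
      shape = f$shape, location = f$location, scale = f$scale,
      bandwidth = if (f$family == "kde") f$kde$bandwidth else NA_real_,
      p_normal = f$ks_pvalues[["normal"]],
      p_lognormal = f$ks_pvalues[["lognormal"]],
      p_gamma = f$ks_pvalues[["gamma"]],
      sample_size = f$sample_size)
  }
  list(fits = fits, table = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
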