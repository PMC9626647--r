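# Fixtures and independent brute-force oracles used across the suite.
# Oracles are written as plain rule-checkers (explicit loops, no shared
# code with the package internals) so they stay independent of the
# implementation they verify.

# small random gridded field: dims (n_t, n_lat, n_lon), border of land
# optional, missing fraction applied uniformly at random over ocean
random_field <- function(n_t = 6, n_lat = 6, n_lon = 6, miss_frac = 0.3,
                         land_border = FALSE, seed = 1) {
  set.seed(seed)
  land <- matrix(FALSE, n_lat, n_lon)
  if (land_border) {
    land[c(1, n_lat), ] <- TRUE
    land[, c(1, n_lon)] <- TRUE
  }
  vals <- array(exp(rnorm(n_t * n_lat * n_lon, 0, 0.5)), c(n_t, n_lat, n_lon))
  miss <- array(runif(n_t * n_lat * n_lon) < miss_frac, c(n_t, n_lat, n_lon))
  for (t in seq_len(n_t)) miss[t, , ][land] <- FALSE
  vals[miss] <- NA_real_
  gridded_field(vals, as.Date("2000-01-01") + 8 * (seq_len(n_t) - 1),
                lat = seq_len(n_lat) - 0.5, lon = seq_len(n_lon) - 0.5,
                land = land, missing = miss)
}

# Brute-force single-axis fill: triple loop, explicit rule check.
# A missing ocean pixel takes the mean of its valid immediate neighbours
# along `axis` in the ORIGINAL values; no valid neighbour leaves it NA.
oracle_fill_pass <- function(field, axis) {
  v <- field$values
  out <- v
  d <- dim(v)
  for (t in seq_len(d[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    if (!field$missing[t, i, j]) next
    nb <- c()
    if (axis == "time") {
      if (t > 1) nb <- c(nb, v[t - 1, i, j])
      if (t < d[1]) nb <- c(nb, v[t + 1, i, j])
    } else if (axis == "lat") {
      if (i > 1) nb <- c(nb, v[t, i - 1, j])
      if (i < d[2]) nb <- c(nb, v[t, i + 1, j])
    } else {
      if (j > 1) nb <- c(nb, v[t, i, j - 1])
      if (j < d[3]) nb <- c(nb, v[t, i, j + 1])
    }
    nb <- nb[!is.na(nb)]
    if (length(nb)) out[t, i, j] <- mean(nb)
  }
  out
}

# sequential lon -> lat -> time oracle; returns the values array
oracle_interpolate <- function(field) {
  for (axis in c("lon", "lat", "time")) {
    filled <- oracle_fill_pass(field, axis)
    field$missing <- field$missing & is.na(filled)
    field$values <- filled
  }
  field$values
}

# first index in window strictly above factor * median of whole series
oracle_initiation <- function(series, factor, window) {
  thr <- factor * median(series)
  for (k in window) if (series[k] > thr) return(k)
  NA_integer_
}

# earliest argmax inside the window
oracle_peak <- function(series, window) {
  best <- window[1]
  for (k in window) if (series[k] > series[best]) best <- k
  best
}

# quick synthetic pipeline run at test scale, returning everything
run_small_pipeline <- function(seed = 1, n_members = 50, summer_gap = 0.4,
                               offseason_gap = 0.1, params = synth_params()) {
  truth <- simulate_chl_field(params, seed = seed)
  gapped <- apply_cloud_gaps(truth, summer_gap = summer_gap,
                             offseason_gap = offseason_gap, seed = seed + 1000)
  s1 <- optimal_interpolate(gapped)
  fits <- fit_field(s1)
  ens <- generate_ensembles(s1, fits$fits, n_members = n_members,
                            seed = seed + 2000)
  list(truth = truth, gapped = gapped, step1 = s1, fits = fits, ens = ens)
}
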