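# Shared fixtures: all synthetic, built in code at test time.

# Brute-force pairwise-slope median, kept deliberately naive as the oracle
# for the Sen estimator.
oracle_sen <- function(values, years) {
  slopes <- c()
  n <- length(values)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      slopes <- c(slopes, (values[j] - values[i]) / (years[j] - years[i]))
    }
  }
  median(slopes)
}

# Brute-force Mann-Kendall score.
oracle_mk_s <- function(values) {
  s <- 0L
  n <- length(values)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(values[j] - values[i])
    }
  }
  as.integer(s)
}

# Flat-boundary pair for sampling-design tests.
flat_boundaries <- function(lon = c(-120, -100), south = 53.01,
                            north = 61.01) {
  bt_boundaries(data.frame(lon = lon, lat = rep(south, length(lon))),
                data.frame(lon = lon, lat = rep(north, length(lon))))
}

# Small landscape shared by several test files (generated once per run).
tiny_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_landscape(landscape_config(
        lon_range = c(-106, -103), lat_range = c(51, 64), res = 0.05,
        seed = 42L))
    }
    cache
  }
})

# Exponential-covariance Gaussian field sampled at scattered points, by
# Cholesky factorization — independent of the package's FFT simulator.
simulate_exp_points <- function(n, lon_range, lat_range, practical_range_km,
                                sd, seed, nugget_sd = 0) {
  set.seed(seed)
  lon <- runif(n, lon_range[1], lon_range[2])
  lat <- runif(n, lat_range[1], lat_range[2])
  km <- borealtrends:::project_km(lon, lat)
  D <- as.matrix(dist(cbind(km$x, km$y)))
  S <- sd^2 * exp(-3 * D / practical_range_km)
  L <- chol(S + diag(1e-10, n))
  value <- drop(crossprod(L, rnorm(n)))
  if (nugget_sd > 0) value <- value + rnorm(n, 0, nugget_sd)
  data.frame(lon = lon, lat = lat, value = value)
}

# True trend profile of a landscape config.
g_of <- function(config) {
  borealtrends:::trend_profile_fun(config$trend_profile)
}
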