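# Seeded synthetic-landscape generator: a rectangular geographic domain with
# two sinusoidal biome boundary lines, annual tree-cover grids carrying a
# known SBD-dependent trend plus AR(1) interannual noise and spatially
# correlated heterogeneity, patchy fire/harvest disturbances with years and
# recovery, a categorical land-cover grid, coarse climate series with a
# warming trend, and elevation. Every generated bundle carries a ground-truth
# ledger sufficient to score pipeline estimates.

#' Configuration of a synthetic landscape
#'
#' All arguments have defaults describing the reference landscape used in
#' tests and examples: a 10 x 15 degree domain at 0.01 degree resolution
#' (a desk-scale stand-in for 250 m continental rasters), 20 annual cover
#' grids (2000-2019), a south-north trend profile with losses near the
#' southern boundary and gains in the northern interior, AR(1) interannual
#' noise, exponentially correlated spatial heterogeneity, patchy
#' disturbances since 1985 with slower recovery toward the south, and a
#' ~0.04 degC/yr warming trend since 1980.
#'
#' @param lon_range,lat_range Domain extent in degrees.
#' @param res Grid resolution in degrees.
#' @param years Calendar years of the cover stack.
#' @param south_lat,north_lat Mean latitudes of the two boundary lines.
#' @param wiggle_amp,wiggle_period Amplitude (deg lat) and period (deg lon)
#'   of the sinusoidal boundary wiggle.
#' @param trend_profile List with vectors `sbd` and `rate` (percent/yr):
#'   control points of the true trend profile `g(sbd)`, interpolated by a
#'   natural cubic spline.
#' @param baseline_profile List with vectors `sbd` and `cover` (percent):
#'   control points of the baseline cover profile, linearly interpolated.
#' @param ar1_rho,temporal_sd AR(1) coefficient and stationary SD (percent)
#'   of the per-pixel interannual noise.
#' @param spatial_sd,spatial_range_km SD (percent) and practical range (km)
#'   of the static spatially correlated cover heterogeneity.
#' @param trend_field_sd,trend_field_range_km SD (percent/yr) and practical
#'   range (km) of the spatially correlated perturbation added to the trend
#'   profile; this is what gives the trend field its spatial
#'   autocorrelation.
#' @param disturbance_density Expected disturbance patches per square
#'   degree.
#' @param disturbance_radius_range Patch radius range in degrees.
#' @param disturbance_years Year range of disturbance events.
#' @param fire_fraction Probability that a patch is wildfire (vs harvest).
#' @param fire_drop,harvest_drop Immediate cover loss (percent) of each
#'   disturbance type.
#' @param recovery_rate_base,recovery_rate_sbd Recovery in percent/yr at
#'   SBD 0 and its linear SBD gradient; positive gradient means slower
#'   recovery toward the south.
#' @param lake_density,lake_radius_range Water-body patch process
#'   (per square degree; radii in degrees) stamped into the land-cover grid.
#' @param climate_res Climate grid resolution in degrees.
#' @param climate_years Years of the annual climate series.
#' @param mat_base,mat_lapse Mean annual temperature (degC) at the domain's
#'   mid latitude and its decrease per degree latitude northward.
#' @param warming_rate Linear warming in degC/yr over `climate_years`.
#' @param map_base,map_lapse,map_trend Mean annual precipitation (mm) at mid
#'   latitude, its per-degree-latitude gradient, and its linear trend
#'   (mm/yr).
#' @param climate_sd_t,climate_sd_p Interannual climate noise SDs.
#' @param elevation_base,elevation_sd,elevation_range_km Elevation field:
#'   mean (m), SD of the correlated component and its practical range.
#' @param seed Integer seed; identical config + seed reproduce identical
#'   landscapes.
#' @return A list of class `bt_landscape_config`.
#' @export
landscape_config <- function(
    lon_range = c(-110, -100), lat_range = c(50, 65), res = 0.01,
    years = 2000:2019,
    south_lat = 53.5, north_lat = 61.5,
    wiggle_amp = 0.8, wiggle_period = 6,
    trend_profile = list(
      sbd = c(-1.5, -1.25, -1, 0.5, 1, 1.25, 1.5),
      rate = c(0, 0, -0.13, 0.22, 0.05, 0, 0)
    ),
    baseline_profile = list(
      sbd = c(-1.5, -1.25, -1, -0.5, 0, 0.5, 1, 1.25, 1.5),
      cover = c(6, 10, 14, 45, 55, 50, 15, 9, 4)
    ),
    ar1_rho = 0.3, temporal_sd = 2,
    spatial_sd = 4, spatial_range_km = 133,
    trend_field_sd = 0.08, trend_field_range_km = 133,
    disturbance_density = 2.2,
    disturbance_radius_range = c(0.05, 0.2),
    disturbance_years = c(1985, 2019),
    fire_fraction = 0.7,
    fire_drop = 25, harvest_drop = 35,
    recovery_rate_base = 2.5, recovery_rate_sbd = 1.0,
    lake_density = 1.5, lake_radius_range = c(0.02, 0.08),
    climate_res = 0.25, climate_years = 1980:2019,
    mat_base = 0.5, mat_lapse = 0.6, warming_rate = 0.04,
    map_base = 480, map_lapse = -12, map_trend = 0.5,
    climate_sd_t = 0.7, climate_sd_p = 40,
    elevation_base = 350, elevation_sd = 120, elevation_range_km = 200,
    seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(diff(lon_range) > 0, diff(lat_range) > 0, res > 0,
            abs(ar1_rho) < 1, spatial_range_km > 0, trend_field_range_km > 0,
            north_lat > south_lat)
  structure(cfg, class = "bt_landscape_config")
}

trend_profile_fun <- function(profile) {
  stats::splinefun(profile$sbd, profile$rate, method = "natural")
}

baseline_profile_fun <- function(profile) {
  stats::approxfun(profile$sbd, profile$cover, rule = 2)
}

# Continuous per-pixel SBD: -1/+1 at the boundary lines, linear in latitude
# between them, +/-0.5 over one 20-plot extension span (1 degree at the
# 0.05-degree plot size) beyond them, capped at +/-1.5.
sbd_field <- function(lat, s_lat, n_lat, ext_deg = 1) {
  inside <- -1 + 2 * (lat - s_lat) / (n_lat - s_lat)
  south <- -1 - 0.5 * (s_lat - lat) / ext_deg
  north <- 1 + 0.5 * (lat - n_lat) / ext_deg
  out <- ifelse(lat < s_lat, south, ifelse(lat > n_lat, north, inside))
  pmax(pmin(out, 1.5), -1.5)
}

#' Stationary Gaussian random field with exponential covariance
#'
#' Simulates a zero-mean field on a regular grid whose covariance is
#' `sd^2 * exp(-d / a)` with `a = practical_range_km / 3`, using circulant
#' embedding and the FFT. Small negative embedding eigenvalues are clamped
#' to zero (the standard approximation, negligible at these range/domain
#' ratios).
#'
#' @param nrow,ncol Grid dimensions (rows south to north).
#' @param cell_km Cell size in km as `c(dx, dy)` (or one number for square
#'   cells).
#' @param practical_range_km Distance at which correlation drops to ~0.05.
#' @param sd Marginal standard deviation; 0 returns a zero field.
#' @param seed Integer seed.
#' @return A `nrow` x `ncol` numeric matrix.
#' @export
spatial_field <- function(nrow, ncol, cell_km, practical_range_km, sd,
                          seed) {
  if (length(cell_km) == 1L) cell_km <- rep(cell_km, 2L)
  if (sd == 0) {
    return(matrix(0, nrow, ncol))
  }
  stopifnot(practical_range_km > 0, sd > 0)
  a <- practical_range_km / 3
  M <- stats::nextn(2L * nrow, c(2, 3))
  N <- stats::nextn(2L * ncol, c(2, 3))
  di <- pmin(0:(M - 1L), M - (0:(M - 1L))) * cell_km[2L]
  dj <- pmin(0:(N - 1L), N - (0:(N - 1L))) * cell_km[1L]
  dmat <- sqrt(outer(di^2, dj^2, "+"))
  C <- sd^2 * exp(-dmat / a)
  lambda <- Re(stats::fft(C))
  lambda[lambda < 0] <- 0
  set.seed(seed)
  xi <- matrix(stats::rnorm(M * N), M, N) +
    1i * matrix(stats::rnorm(M * N), M, N)
  Z <- stats::fft(sqrt(lambda / (M * N)) * xi)
  Re(Z)[seq_len(nrow), seq_len(ncol)]
}

#' Additive cover term of a disturbance event
#'
#' A step drop of `drop` percent at the event year followed by linear
#' recovery at `recovery_rate` percent/yr, capped at full recovery.
#'
#' @param year Year(s) at which to evaluate the term.
#' @param event_year Disturbance year (`NA` means no event: zero term).
#' @param drop Immediate cover loss in percent (> 0).
#' @param recovery_rate Recovery in percent/yr (>= 0).
#' @return The (non-positive) additive cover term; vectors recycle.
#' @export
disturbance_effect <- function(year, event_year, drop, recovery_rate) {
  out <- ifelse(is.na(event_year) | year < event_year, 0,
                pmin(0, -drop + recovery_rate * (year - event_year)))
  out[is.na(event_year)] <- 0
  out
}

#' Generate a synthetic landscape bundle
#'
#' Realizes one landscape from a [landscape_config()]: boundary polylines,
#' annual cover stack, land-cover grid, disturbance type/year grids, climate
#' series, elevation, and a ground-truth ledger (per-pixel true trend, the
#' noise-free profile `g(sbd)`, true SBD, and the disturbance patch table).
#' Per-pixel cover follows
#' `clip(baseline(sbd) + (g(sbd) + trend_field) * (t - t0) + spatial_field
#' + AR1_t + disturbance_effect, 0, 100)`.
#'
#' @param config A [landscape_config()].
#' @return A list of class `bt_landscape` with elements `config`,
#'   `boundaries`, `cover` ([bt_stack()]), `landcover`, `dist_type`,
#'   `dist_year`, `elevation` ([bt_grid()]s), `climate` ([bt_climate()]),
#'   `truth` (list: `trend`, `g`, `sbd` grids; `patches` table; true climate
#'   rates), and `clip_fraction` (share of clipped cover values).
#' @export
generate_landscape <- function(config = landscape_config()) {
  cfg <- config
  lon0 <- cfg$lon_range[1]
  lat0 <- cfg$lat_range[1]
  nx <- round(diff(cfg$lon_range) / cfg$res)
  ny <- round(diff(cfg$lat_range) / cfg$res)
  if (nx < 10 || ny < 10) stop("degenerate domain: fewer than 10 cells")
  lon <- lon0 + (seq_len(nx) - 0.5) * cfg$res
  lat <- lat0 + (seq_len(ny) - 0.5) * cfg$res
  lat_mid <- mean(cfg$lat_range)
  cell_km <- c(cfg$res * KM_PER_DEG_LON_EQ * cos(lat_mid * pi / 180),
               cfg$res * KM_PER_DEG_LAT)

  # boundary polylines (sinusoidal wiggle, phase-shifted between the lines)
  blon <- seq(cfg$lon_range[1], cfg$lon_range[2], by = 0.1)
  s_line <- cfg$south_lat +
    cfg$wiggle_amp * sin(2 * pi * (blon - lon0) / cfg$wiggle_period)
  n_line <- cfg$north_lat +
    cfg$wiggle_amp * sin(2 * pi * (blon - lon0) / cfg$wiggle_period +
                           pi / 3)
  boundaries <- bt_boundaries(data.frame(lon = blon, lat = s_line),
                              data.frame(lon = blon, lat = n_line))

  # per-pixel SBD (rows = lat, cols = lon)
  s_at <- boundary_lat(boundaries, "southern", lon)
  n_at <- boundary_lat(boundaries, "northern", lon)
  sbd <- matrix(NA_real_, ny, nx)
  for (j in seq_len(nx)) {
    sbd[, j] <- sbd_field(lat, s_at[j], n_at[j])
  }

  g_fun <- trend_profile_fun(cfg$trend_profile)
  b_fun <- baseline_profile_fun(cfg$baseline_profile)
  g <- matrix(g_fun(as.vector(sbd)), ny, nx)
  baseline <- matrix(b_fun(as.vector(sbd)), ny, nx)

  sfield <- spatial_field(ny, nx, cell_km, cfg$spatial_range_km,
                          cfg$spatial_sd, derive_seed(cfg$seed, "sfield"))
  tfield <- spatial_field(ny, nx, cell_km, cfg$trend_field_range_km,
                          cfg$trend_field_sd, derive_seed(cfg$seed, "tfield"))
  true_trend <- g + tfield

  # land cover: SBD-banded class probabilities, then lake patches
  set.seed(derive_seed(cfg$seed, "landcover"))
  landcover <- matrix(NA_integer_, ny, nx)
  bands <- list(
    list(lo = -Inf, hi = -1,
         codes = c(LC_RETAINED[c("non_woody", "broadleaf", "mixed")],
                   LC_EXCLUDED[c("cropland", "urban", "bare")]),
         probs = c(0.38, 0.25, 0.17, 0.13, 0.02, 0.05)),
    list(lo = -1, hi = -0.3,
         codes = c(LC_RETAINED[c("needleleaf", "mixed", "broadleaf",
                                 "non_woody", "shrubs", "unknown_forest")],
                   LC_EXCLUDED["wetland"]),
         probs = c(0.38, 0.22, 0.13, 0.08, 0.06, 0.06, 0.07)),
    list(lo = -0.3, hi = 0.5,
         codes = c(LC_RETAINED[c("needleleaf", "mixed", "shrubs",
                                 "non_woody", "unknown_forest")],
                   LC_EXCLUDED["wetland"]),
         probs = c(0.58, 0.1, 0.1, 0.1, 0.06, 0.06)),
    list(lo = 0.5, hi = 1,
         codes = c(LC_RETAINED[c("needleleaf", "shrubs", "non_woody")],
                   LC_EXCLUDED["bare"]),
         probs = c(0.45, 0.27, 0.23, 0.05)),
    list(lo = 1, hi = Inf,
         codes = c(LC_RETAINED[c("shrubs", "non_woody")],
                   LC_EXCLUDED[c("bare", "snow_ice")]),
         probs = c(0.33, 0.44, 0.17, 0.06))
  )
  for (b in bands) {
    idx <- which(sbd > b$lo & sbd <= b$hi)
    if (length(idx)) {
      landcover[idx] <- sample(as.integer(b$codes), length(idx),
                               replace = TRUE, prob = b$probs)
    }
  }
  area_deg2 <- diff(cfg$lon_range) * diff(cfg$lat_range)
  stamp_patches <- function(n, radius_range, assign) {
    if (n == 0L) return(invisible(NULL))
    cx <- stats::runif(n, cfg$lon_range[1], cfg$lon_range[2])
    cy <- stats::runif(n, cfg$lat_range[1], cfg$lat_range[2])
    r <- stats::runif(n, radius_range[1], radius_range[2])
    for (p in seq_len(n)) {
      jj <- which(abs(lon - cx[p]) <= r[p])
      ii <- which(abs(lat - cy[p]) <= r[p])
      if (!length(ii) || !length(jj)) next
      d2 <- outer((lat[ii] - cy[p])^2, (lon[jj] - cx[p])^2, "+")
      assign(p, ii, jj, d2 <= r[p]^2)
    }
    data.frame(patch = seq_len(n), lon = cx, lat = cy, radius = r)
  }
  n_lakes <- stats::rpois(1L, cfg$lake_density * area_deg2)
  stamp_patches(n_lakes, cfg$lake_radius_range, function(p, ii, jj, mask) {
    sub <- landcover[ii, jj, drop = FALSE]
    sub[mask] <- LC_EXCLUDED[["water"]]
    landcover[ii, jj] <<- sub
  })

  # disturbance patches (type 1 = fire, 2 = harvest) with event years
  set.seed(derive_seed(cfg$seed, "disturbance"))
  dist_type <- matrix(0L, ny, nx)
  dist_year <- matrix(NA_real_, ny, nx)
  n_pat <- stats::rpois(1L, cfg$disturbance_density * area_deg2)
  types <- if (n_pat) {
    ifelse(stats::runif(n_pat) < cfg$fire_fraction, 1L, 2L)
  } else {
    integer(0)
  }
  yrs_pat <- if (n_pat) {
    sample(seq(cfg$disturbance_years[1], cfg$disturbance_years[2]), n_pat,
           replace = TRUE)
  } else {
    integer(0)
  }
  patches <- stamp_patches(n_pat, cfg$disturbance_radius_range,
                           function(p, ii, jj, mask) {
    tsub <- dist_type[ii, jj, drop = FALSE]
    ysub <- dist_year[ii, jj, drop = FALSE]
    tsub[mask] <- types[p]
    ysub[mask] <- yrs_pat[p]
    dist_type[ii, jj] <<- tsub
    dist_year[ii, jj] <<- ysub
  })
  if (!is.null(patches)) {
    patches$type <- ifelse(types == 1L, "fire", "harvest")
    patches$year <- yrs_pat
  } else {
    patches <- data.frame(patch = integer(0), lon = numeric(0),
                          lat = numeric(0), radius = numeric(0),
                          type = character(0), year = integer(0))
  }

  # annual cover stack with AR(1) noise and disturbance recovery
  set.seed(derive_seed(cfg$seed, "ar1"))
  nt <- length(cfg$years)
  t0 <- cfg$years[1]
  cover <- array(NA_real_, c(ny, nx, nt))
  disturbed <- which(dist_type > 0L)
  # a disturbance cannot remove more cover than the site carries
  drop_v <- pmin(ifelse(dist_type[disturbed] == 1L, cfg$fire_drop,
                        cfg$harvest_drop), baseline[disturbed])
  rate_v <- pmax(0.5, cfg$recovery_rate_base +
                   cfg$recovery_rate_sbd * sbd[disturbed])
  eyear_v <- dist_year[disturbed]
  eps <- matrix(stats::rnorm(ny * nx, 0, cfg$temporal_sd), ny, nx)
  innov_sd <- cfg$temporal_sd * sqrt(1 - cfg$ar1_rho^2)
  n_clip <- 0
  for (ti in seq_len(nt)) {
    if (ti > 1L) {
      eps <- cfg$ar1_rho * eps +
        matrix(stats::rnorm(ny * nx, 0, innov_sd), ny, nx)
    }
    yr <- cfg$years[ti]
    expected <- baseline + true_trend * (yr - t0)
    if (length(disturbed)) {
      expected[disturbed] <- expected[disturbed] +
        disturbance_effect(yr, eyear_v, drop_v, rate_v)
    }
    expected <- pmax(expected, 0.3)  # cover cannot be driven below zero
    # fractional-cover noise shrinks toward the 0 and 100% bounds; damp the
    # noise fields with the usual sqrt(p(100-p)) shape (floor 0.15)
    damp <- pmax(sqrt(pmin(pmax(expected, 0.5), 99.5) *
                        (100 - pmin(pmax(expected, 0.5), 99.5))) / 50, 0.15)
    slice <- expected + damp * (sfield + eps)
    n_clip <- n_clip + sum(slice < 0 | slice > 100)
    cover[, , ti] <- pmax(pmin(slice, 100), 0)
  }

  # climate: coarse annual series with a linear warming trend
  set.seed(derive_seed(cfg$seed, "climate"))
  clon <- seq(cfg$lon_range[1] + cfg$climate_res / 2, cfg$lon_range[2],
              by = cfg$climate_res)
  clat <- seq(cfg$lat_range[1] + cfg$climate_res / 2, cfg$lat_range[2],
              by = cfg$climate_res)
  ncy <- length(cfg$climate_years)
  mat <- array(NA_real_, c(length(clat), length(clon), ncy))
  map <- array(NA_real_, c(length(clat), length(clon), ncy))
  base_t <- cfg$mat_base - cfg$mat_lapse * (clat - lat_mid)
  base_p <- pmax(0, cfg$map_base + cfg$map_lapse * (clat - lat_mid))
  for (ti in seq_len(ncy)) {
    dy <- cfg$climate_years[ti] - cfg$climate_years[1]
    mat[, , ti] <- outer(base_t, rep(1, length(clon))) +
      cfg$warming_rate * dy +
      matrix(stats::rnorm(length(clat) * length(clon), 0, cfg$climate_sd_t),
             length(clat), length(clon))
    map[, , ti] <- pmax(0, outer(base_p, rep(1, length(clon))) +
      cfg$map_trend * dy +
      matrix(stats::rnorm(length(clat) * length(clon), 0, cfg$climate_sd_p),
             length(clat), length(clon)))
  }
  climate <- bt_climate(clon, clat, cfg$climate_years, mat, map)

  elev_vals <- cfg$elevation_base +
    spatial_field(ny, nx, cell_km, cfg$elevation_range_km,
                  cfg$elevation_sd, derive_seed(cfg$seed, "elevation"))
  elevation <- bt_grid(pmax(elev_vals, 0), lon0, lat0, cfg$res)

  structure(list(
    config = cfg,
    boundaries = boundaries,
    cover = bt_stack(cover, cfg$years, lon0, lat0, cfg$res),
    landcover = bt_grid(landcover, lon0, lat0, cfg$res),
    dist_type = bt_grid(dist_type, lon0, lat0, cfg$res),
    dist_year = bt_grid(dist_year, lon0, lat0, cfg$res),
    elevation = elevation,
    climate = climate,
    truth = list(
      trend = bt_grid(true_trend, lon0, lat0, cfg$res),
      g = bt_grid(g, lon0, lat0, cfg$res),
      sbd = bt_grid(sbd, lon0, lat0, cfg$res),
      patches = patches,
      warming_rate = cfg$warming_rate,
      map_trend = cfg$map_trend
    ),
    clip_fraction = n_clip / (as.numeric(ny) * nx * nt)
  ), class = "bt_landscape")
}

#' @export
print.bt_landscape <- function(x, ...) {
  d <- dim(x$cover$values)
  cat(sprintf(
    "<bt_landscape> %d x %d cells at %g deg, %d years (%d-%d)\n",
    d[1], d[2], x$config$res, d[3], min(x$cover$years),
    max(x$cover$years)))
  cat(sprintf("  disturbance patches: %d; clipped cover values: %.3g%%\n",
              nrow(x$truth$patches), 100 * x$clip_fraction))
  invisible(x)
}

#' Write a landscape bundle to a directory
#'
#' Plain-text layout: `cover/YYYY.asc` per year, `landcover.asc`,
#' `disturbance_type.asc`, `disturbance_year.asc`, `elevation.asc`,
#' `truth_trend.asc`, `truth_g.asc`, `truth_sbd.asc`,
#' `boundaries.geojson`, `climate.csv` (long format), `patches.csv`,
#' `config.yaml`.
#'
#' @param landscape A [generate_landscape()] result.
#' @param dir Output directory (created if needed).
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(file.path(dir, "cover"), recursive = TRUE, showWarnings = FALSE)
  st <- landscape$cover
  for (ti in seq_along(st$years)) {
    write_ascii_grid(bt_grid(st$values[, , ti], st$lon0, st$lat0, st$res),
                     file.path(dir, "cover",
                               sprintf("%d.asc", st$years[ti])))
  }
  write_ascii_grid(landscape$landcover, file.path(dir, "landcover.asc"))
  write_ascii_grid(landscape$dist_type,
                   file.path(dir, "disturbance_type.asc"))
  write_ascii_grid(landscape$dist_year,
                   file.path(dir, "disturbance_year.asc"))
  write_ascii_grid(landscape$elevation, file.path(dir, "elevation.asc"))
  write_ascii_grid(landscape$truth$trend, file.path(dir, "truth_trend.asc"))
  write_ascii_grid(landscape$truth$g, file.path(dir, "truth_g.asc"))
  write_ascii_grid(landscape$truth$sbd, file.path(dir, "truth_sbd.asc"))
  write_boundaries_geojson(landscape$boundaries,
                           file.path(dir, "boundaries.geojson"))
  cl <- landscape$climate
  grid_idx <- expand.grid(i = seq_along(cl$lat), j = seq_along(cl$lon))
  rows <- lapply(seq_along(cl$years), function(ti) {
    data.frame(lon = cl$lon[grid_idx$j], lat = cl$lat[grid_idx$i],
               year = cl$years[ti],
               mat = cl$mat[cbind(grid_idx$i, grid_idx$j, ti)],
               map = cl$map[cbind(grid_idx$i, grid_idx$j, ti)])
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "climate.csv"),
                   row.names = FALSE)
  utils::write.csv(landscape$truth$patches, file.path(dir, "patches.csv"),
                   row.names = FALSE)
  cfg <- landscape$config
  cfg$years <- as.integer(cfg$years)
  cfg$climate_years <- as.integer(cfg$climate_years)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a landscape bundle from a directory
#'
#' Inverse of [write_landscape()]; the ground-truth patch table and climate
#' series are restored, and the configuration is re-classed.
#'
#' @param dir Directory written by [write_landscape()].
#' @return A `bt_landscape`.
#' @export
read_landscape <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  for (nm in c("lon_range", "lat_range", "trend_profile",
               "baseline_profile")) {
    cfg[[nm]] <- if (is.list(cfg[[nm]])) {
      lapply(cfg[[nm]], unlist)
    } else {
      unlist(cfg[[nm]])
    }
  }
  cfg <- do.call(landscape_config, cfg[names(cfg) %in%
                                         names(formals(landscape_config))])
  years <- sort(as.integer(sub("\\.asc$", "",
                               list.files(file.path(dir, "cover")))))
  grids <- lapply(years, function(y) {
    read_ascii_grid(file.path(dir, "cover", sprintf("%d.asc", y)))
  })
  g1 <- grids[[1L]]
  cov <- array(NA_real_, c(dim(g1$values), length(years)))
  for (ti in seq_along(years)) cov[, , ti] <- grids[[ti]]$values
  lc <- read_ascii_grid(file.path(dir, "landcover.asc"))
  lc$values <- matrix(as.integer(lc$values), nrow(lc$values))
  dt <- read_ascii_grid(file.path(dir, "disturbance_type.asc"))
  dt$values <- matrix(as.integer(dt$values), nrow(dt$values))
  clim_df <- utils::read.csv(file.path(dir, "climate.csv"))
  clon <- sort(unique(clim_df$lon))
  clat <- sort(unique(clim_df$lat))
  cyears <- sort(unique(clim_df$year))
  mat <- array(NA_real_, c(length(clat), length(clon), length(cyears)))
  map <- mat
  idx <- cbind(match(clim_df$lat, clat), match(clim_df$lon, clon),
               match(clim_df$year, cyears))
  mat[idx] <- clim_df$mat
  map[idx] <- clim_df$map
  structure(list(
    config = cfg,
    boundaries = read_boundaries_geojson(file.path(dir,
                                                   "boundaries.geojson")),
    cover = bt_stack(cov, years, g1$lon0, g1$lat0, g1$res),
    landcover = lc,
    dist_type = dt,
    dist_year = read_ascii_grid(file.path(dir, "disturbance_year.asc")),
    elevation = read_ascii_grid(file.path(dir, "elevation.asc")),
    climate = bt_climate(clon, clat, cyears, mat, map),
    truth = list(
      trend = read_ascii_grid(file.path(dir, "truth_trend.asc")),
      g = read_ascii_grid(file.path(dir, "truth_g.asc")),
      sbd = read_ascii_grid(file.path(dir, "truth_sbd.asc")),
      patches = utils::read.csv(file.path(dir, "patches.csv")),
      warming_rate = cfg$warming_rate,
      map_trend = cfg$map_trend
    ),
    clip_fraction = NA_real_
  ), class = "bt_landscape")
}
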