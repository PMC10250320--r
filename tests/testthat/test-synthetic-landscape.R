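quiet_config <- function(...) {
  # noise-free landscape: flat 40% baseline, zero trend, no disturbances
  landscape_config(
    lon_range = c(-105, -103), lat_range = c(52, 63), res = 0.05,
    baseline_profile = list(sbd = c(-1.5, 1.5), cover = c(40, 40)),
    trend_profile = list(sbd = c(-1.5, 0, 1.5), rate = c(0, 0, 0)),
    ar1_rho = 0, temporal_sd = 0, spatial_sd = 0, trend_field_sd = 0,
    disturbance_density = 0, lake_density = 0,
    climate_sd_t = 0, climate_sd_p = 0, seed = 71, ...)
}

test_that("noise-free zero-trend landscape is constant at the baseline", {
  ls <- generate_landscape(quiet_config())
  expect_true(all(ls$cover$values == 40))
  expect_equal(ls$clip_fraction, 0)
})

test_that("noise-free landscape reproduces g(sbd) exactly per pixel", {
  cfg <- quiet_config()
  cfg$trend_profile <- list(sbd = c(-1.5, -1.25, -1, 0.5, 1, 1.25, 1.5),
                            rate = c(0, 0, -0.13, 0.22, 0.05, 0, 0))
  ls <- generate_landscape(cfg)
  set.seed(72)
  cells <- cbind(sample(nrow(ls$truth$trend$values), 40),
                 sample(ncol(ls$truth$trend$values), 40))
  for (k in seq_len(nrow(cells))) {
    series <- ls$cover$values[cells[k, 1], cells[k, 2], ]
    expect_equal(sen_slope(series, ls$cover$years),
                 ls$truth$trend$values[cells[k, 1], cells[k, 2]],
                 tolerance = 1e-10)
  }
  # the truth ledger's trend equals g at the ledger's own sbd
  gfun <- g_of(cfg)
  expect_equal(as.vector(ls$truth$trend$values),
               gfun(as.vector(ls$truth$sbd$values)), tolerance = 1e-12)
})

test_that("disturbance_effect follows drop-and-linear-recovery arithmetic", {
  expect_equal(disturbance_effect(2005, NA, 30, 3), 0)
  expect_equal(disturbance_effect(2010, 2010, 30, 3), -30)
  expect_equal(disturbance_effect(2015, 2010, 30, 3), -15)
  expect_equal(disturbance_effect(2021, 2010, 30, 3), 0)  # full recovery
  expect_equal(disturbance_effect(2009, 2010, 30, 3), 0)  # before event
  # pre-window event fully recovered by 2000 leaves the window untouched
  expect_true(all(disturbance_effect(2000:2019, 1990, 25, 3) == 0))
})

test_that("spatial_field has the requested variance and is seeded", {
  expect_true(all(spatial_field(50, 50, 1, 60, 0, seed = 1) == 0))
  f <- spatial_field(300, 300, c(2, 2), 60, 1.5, seed = 73)
  expect_lt(abs(var(as.vector(f)) - 1.5^2) / 1.5^2, 0.10)
  expect_identical(spatial_field(40, 40, 1, 50, 1, seed = 5),
                   spatial_field(40, 40, 1, 50, 1, seed = 5))
  expect_false(identical(spatial_field(40, 40, 1, 50, 1, seed = 5),
                         spatial_field(40, 40, 1, 50, 1, seed = 6)))
})

test_that("the field's variogram closes the loop with the model fit", {
  res <- 0.03
  lat0 <- 50
  latm <- lat0 + 160 * res / 2
  dx <- res * 111.32 * cos(latm * pi / 180)
  dy <- res * 110.574
  prs <- vapply(1:3, function(s) {
    fld <- spatial_field(160, 160, c(dx, dy), 90, 1, seed = 80 + s)
    pts <- sample_random_points(bt_grid(fld, -110, lat0, res), 1200,
                                seed = 90 + s)
    fit <- fit_variogram_model(empirical_variogram(pts, 15, 300),
                               "exponential")
    fit$practical_range
  }, 1)
  expect_lt(abs(median(prs) - 90), 0.5 * 90)
})

test_that("identical config and seed give byte-identical bundles", {
  cfg <- landscape_config(lon_range = c(-105, -104), lat_range = c(53, 59),
                          res = 0.05, seed = 77)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a$cover$values, b$cover$values)
  expect_identical(a$landcover$values, b$landcover$values)
  expect_identical(a$truth$patches, b$truth$patches)
  expect_identical(a$climate$mat, b$climate$mat)
})

test_that("default-parameter landscapes clip under 1% of cover values", {
  # default resolution and latitudinal span on a narrower longitude slice
  ls <- generate_landscape(landscape_config(lon_range = c(-106, -104),
                                            seed = 3))
  expect_lt(ls$clip_fraction, 0.01)
  expect_gte(min(ls$cover$values), 0)
  expect_lte(max(ls$cover$values), 100)
})

test_that("the ground-truth ledger is sufficient to score estimates", {
  ls <- tiny_landscape()
  expect_setequal(
    names(ls$truth),
    c("trend", "g", "sbd", "patches", "warming_rate", "map_trend"))
  expect_identical(dim(ls$truth$trend$values), dim(ls$landcover$values))
  expect_true(all(c("lon", "lat", "radius", "type", "year") %in%
                    names(ls$truth$patches)))
  expect_true(all(ls$truth$sbd$values >= -1.5 & ls$truth$sbd$values <= 1.5))
})
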