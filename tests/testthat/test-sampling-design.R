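test_that("draw_transects honors spacing, determinism and narrow domains", {
  # ~1000 km wide domain at these latitudes
  b <- flat_boundaries(lon = c(-120, -103.4))
  tr <- draw_transects(b, 133, seed = 5)
  expect_lte(nrow(tr), 8L)  # pigeonhole: floor(1000/133) + 1
  expect_gt(nrow(tr), 2L)
  lat_mid <- mean(c(53.01, 61.01))
  if (nrow(tr) > 1) {
    d <- outer(seq_len(nrow(tr)), seq_len(nrow(tr)), function(i, j) {
      haversine_km(tr$lon[i], lat_mid, tr$lon[j], lat_mid)
    })
    expect_true(all(d[upper.tri(d)] >= 133))
  }
  expect_identical(draw_transects(b, 133, seed = 5), tr)
  expect_false(identical(draw_transects(b, 133, seed = 6), tr))

  # domain narrower than the spacing: exactly one transect
  narrow <- flat_boundaries(lon = c(-105, -104.5))
  expect_identical(nrow(draw_transects(narrow, 133, seed = 1)), 1L)
  expect_error(draw_transects(flat_boundaries(lon = c(-105, -104.99)),
                              133, seed = 1), "too narrow")
})

test_that("build_plots counts interior and extension plots correctly", {
  # boundaries placed so the crossing plots are 10 lattice cells apart
  b <- flat_boundaries(south = 53.01, north = 53.46)
  p <- build_plots(-110.025, b, extension_plots = 20)
  expect_identical(nrow(p), 50L)  # 10 interior + 2 x 20 extensions
  expect_identical(sum(p$position == "interior"), 10L)
  p0 <- build_plots(-110.025, b, extension_plots = 0)
  expect_identical(nrow(p0), 10L)
  expect_true(all(p0$position == "interior"))

  # 20 extension plots cover ~1 degree of latitude, ~111 km
  ext <- p[p$position == "north_extension", ]
  span_km <- haversine_km(ext$lon[1], min(ext$lat), ext$lon[1],
                          max(ext$lat)) + 0.05 * 110.574
  expect_gt(span_km, 105)
  expect_lt(span_km, 117)
  expect_error(build_plots(-130, b), "does not cross")
})

test_that("standardized boundary distance meets its endpoint and cap contracts", {
  # crossing plots map to exactly -1 and +1
  expect_equal(standardize_boundary_distance(10, 10, 20), -1)
  expect_equal(standardize_boundary_distance(20, 10, 20), 1)
  # midpoint of N = 5 interior plots is 0
  expect_equal(standardize_boundary_distance(12, 10, 14), 0)
  # 20th extension plot reaches exactly +/-1.5
  expect_equal(standardize_boundary_distance(40, 10, 20), 1.5)
  expect_equal(standardize_boundary_distance(-10, 10, 20), -1.5)
  # capped beyond
  expect_equal(standardize_boundary_distance(60, 10, 20), 1.5)
  expect_error(standardize_boundary_distance(1, 5, 5), "at least 2")
})

test_that("sbd is strictly monotone with latitude on generated transects", {
  ls <- tiny_landscape()
  tr <- draw_transects(ls$boundaries, 60, seed = 9)
  for (i in seq_len(nrow(tr))) {
    p <- build_plots(tr$lon[i], ls$boundaries, transect_id = i)
    expect_true(all(diff(p$lat) > 0))
    expect_true(all(diff(p$sbd) > 0))
    expect_true(all(p$sbd >= -1.5 & p$sbd <= 1.5))
  }
})

test_that("aggregate_plot applies the exclusion and mean rules", {
  plot <- data.frame(lon = -104.975, lat = 55.025, cell = 0.05)
  mk_lc <- function(classes) {
    bt_grid(matrix(classes, 2, 2), -105, 55, 0.025)
  }
  mk_stack <- function(cover_by_pixel) {
    v <- array(rep(matrix(cover_by_pixel, 2, 2), 3), c(2, 2, 3))
    bt_stack(v, 2000:2002, -105, 55, 0.025)
  }
  needle <- LC_RETAINED[["needleleaf"]]
  water <- LC_EXCLUDED[["water"]]
  wetland <- LC_EXCLUDED[["wetland"]]

  a <- aggregate_plot(plot, mk_stack(rep(37, 4)), mk_lc(rep(needle, 4)))
  expect_false(a$excluded)
  expect_equal(a$series, rep(37, 3))
  expect_identical(a$vegetation_class, "needleleaf")

  # water is the single largest class: plot excluded
  b <- aggregate_plot(plot, mk_stack(rep(37, 4)),
                      mk_lc(c(water, water, water, needle)))
  expect_true(b$excluded)
  expect_identical(b$vegetation_class, "excluded")

  # excluded-class pixels are dropped from the mean: {40, 60} -> 50
  c_ <- aggregate_plot(plot, mk_stack(c(40, 60, 99, 0)),
                       mk_lc(c(needle, needle, water, wetland)))
  expect_false(c_$excluded)
  expect_equal(c_$series, rep(50, 3))
  expect_identical(c_$n_retained, 2L)
})

test_that("classify_disturbance implements largest-area and any-sign rules", {
  plot <- data.frame(lon = -104.975, lat = 55.025, cell = 0.05)
  mk <- function(type_px, year_px) {
    list(type = bt_grid(matrix(type_px, 10, 10), -105, 55, 0.005),
         year = bt_grid(matrix(year_px, 10, 10), -105, 55, 0.005))
  }
  # fire 10% (2005) vs harvest 30% (1998): harvest wins, pre-window period
  tp <- c(rep(1L, 10), rep(2L, 30), rep(0L, 60))
  yp <- c(rep(2005, 10), rep(1998, 30), rep(NA, 60))
  g <- mk(tp, yp)
  r <- classify_disturbance(plot, g$type, g$year)
  expect_identical(r$category, "harvest_1985_1999")
  expect_identical(r$year, 1998L)
  expect_equal(r$frac_fire, 0.1)
  expect_equal(r$frac_harvest, 0.3)

  # untouched plot
  g0 <- mk(rep(0L, 100), rep(NA, 100))
  expect_identical(classify_disturbance(plot, g0$type, g0$year)$category,
                   "undisturbed")

  # any sign of disturbance counts: a single fire pixel
  g1 <- mk(c(1L, rep(0L, 99)), c(2010, rep(NA, 99)))
  expect_identical(classify_disturbance(plot, g1$type, g1$year)$category,
                   "fire_2000_2019")

  # equal areas tie-break to fire; year is the largest-area event's year
  g2 <- mk(c(rep(1L, 10), rep(2L, 10), rep(0L, 80)),
           c(rep(2005, 6), rep(2010, 4), rep(2001, 10), rep(NA, 80)))
  r2 <- classify_disturbance(plot, g2$type, g2$year)
  expect_identical(r2$category, "fire_2000_2019")
  expect_identical(r2$year, 2005L)

  # remaining categories reachable
  g3 <- mk(c(rep(2L, 5), rep(0L, 95)), c(rep(2012, 5), rep(NA, 95)))
  expect_identical(classify_disturbance(plot, g3$type, g3$year)$category,
                   "harvest_2000_2019")
  g4 <- mk(c(rep(1L, 5), rep(0L, 95)), c(rep(1990, 5), rep(NA, 95)))
  expect_identical(classify_disturbance(plot, g4$type, g4$year)$category,
                   "fire_1985_1999")
})

test_that("attach_covariates extracts climate means, trends and elevation", {
  plots <- data.frame(lon = -104.9, lat = 55.1, cell = 0.05)
  yrs <- 1980:2019
  uniform <- array(2, c(3, 3, length(yrs)))
  ramp <- array(rep(0.04 * (yrs - 1980), each = 9), c(3, 3, length(yrs)))
  zeros <- array(0, c(3, 3, length(yrs)))
  elev <- bt_grid(matrix(300, 20, 20), -105.5, 54.5, 0.05)
  cl_u <- bt_climate(seq(-105.4, -104.4, 0.5), seq(54.6, 55.6, 0.5), yrs,
                     uniform, zeros)
  out <- attach_covariates(plots, cl_u, elev)
  expect_equal(out$mat, 2)
  expect_equal(out$mat_trend_long, 0)
  expect_equal(out$map, 0)
  expect_equal(out$map_trend_long, 0)
  expect_equal(out$elevation, 300)

  # exact warming ramp recovered by the trend estimator
  cl_r <- bt_climate(seq(-105.4, -104.4, 0.5), seq(54.6, 55.6, 0.5), yrs,
                     ramp, zeros)
  out2 <- attach_covariates(plots, cl_r, elev)
  expect_equal(out2$mat_trend_long, 0.04)
  expect_equal(out2$mat_trend_short, 0.04)
})
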