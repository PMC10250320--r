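test_that("ASCII grid round trip preserves values, mask and georeference", {
  set.seed(101)
  v <- matrix(rnorm(15 * 12, 40, 10), 15, 12)
  v[sample(length(v), 20)] <- NA
  g <- bt_grid(v, -105.35, 52.15, 0.05)
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(g, path)
  g2 <- read_ascii_grid(path)
  expect_equal(g2$values, v, tolerance = 1e-8)
  expect_identical(is.na(g2$values), is.na(v))
  expect_equal(g2$lon0, g$lon0)
  expect_equal(g2$lat0, g$lat0)
  expect_equal(g2$res, g$res)
  expect_error(read_ascii_grid(textConnection("not a grid")))
})

test_that("boundary GeoJSON round trip is exact", {
  b <- bt_boundaries(
    data.frame(lon = seq(-110, -100, 2), lat = 53 + sin(seq(0, 5, 1))),
    data.frame(lon = seq(-110, -100, 2), lat = 61 + cos(seq(0, 5, 1))))
  path <- tempfile(fileext = ".geojson")
  write_boundaries_geojson(b, path)
  b2 <- read_boundaries_geojson(path)
  expect_equal(b2$southern, b$southern)
  expect_equal(b2$northern, b$northern)
})

test_that("plot tables survive the CSV round trip", {
  plots <- data.frame(
    plot_id = c("t001_p0001", "t001_p0002"),
    transect_id = c(1L, 1L),
    lon = c(-104.975, -104.975),
    lat = c(55.025, 55.075),
    sbd = c(-1.003141592653589, 0.5),
    vegetation_class = c("needleleaf", "excluded"),
    disturbance_category = c("fire_2000_2019", "undisturbed"),
    slope_abs = c(0.123456789123456789, NA),
    excluded = c(FALSE, TRUE)
  )
  path <- tempfile(fileext = ".csv")
  write_plot_table(plots, path)
  back <- read_plot_table(path)
  expect_equal(back$sbd, plots$sbd, tolerance = 1e-12)
  expect_equal(back$slope_abs, plots$slope_abs, tolerance = 1e-12)
  expect_identical(back$vegetation_class, plots$vegetation_class)
  expect_identical(back$disturbance_category, plots$disturbance_category)
  expect_identical(back$excluded, plots$excluded)

  # empty table: header-only file, still readable
  write_plot_table(plots[0, ], path)
  expect_identical(nrow(read_plot_table(path)), 0L)
})

test_that("landscape bundles survive the directory round trip", {
  ls <- generate_landscape(landscape_config(
    lon_range = c(-105, -104), lat_range = c(53, 59), res = 0.05,
    seed = 103))
  dir <- tempfile("bundle")
  write_landscape(ls, dir)
  expect_true(file.exists(file.path(dir, "cover", "2000.asc")))
  ls2 <- read_landscape(dir)
  expect_equal(ls2$cover$values, ls$cover$values, tolerance = 1e-8)
  expect_identical(ls2$landcover$values, ls$landcover$values)
  expect_equal(ls2$truth$patches$year, ls$truth$patches$year)
  expect_equal(ls2$climate$mat, ls$climate$mat, tolerance = 1e-8)
  expect_equal(ls2$config$trend_profile$rate, ls$config$trend_profile$rate)
  unlink(dir, recursive = TRUE)
})

test_that("every CLI subcommand runs end to end on a tiny landscape", {
  script <- system.file("cli", "boreal-trends.R", package = "borealtrends")
  expect_true(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = ":"))
  cli <- function(...) {
    out <- suppressWarnings(
      system2(rscript, c(script, ...), stdout = TRUE, stderr = TRUE,
              env = libs))
    status <- attr(out, "status")
    expect_true(is.null(status) || status == 0L,
                label = paste("CLI exit 0 for:", paste(c(...),
                                                       collapse = " "),
                              "|", paste(tail(out, 3), collapse = " / ")))
    out
  }
  wd <- tempfile("cli")
  dir.create(wd)
  bundle <- file.path(wd, "bundle")

  cli("simulate", "--out", bundle, "--seed", "3",
      "--lon-min", "-105", "--lon-max", "-103",
      "--lat-min", "52", "--lat-max", "63", "--res", "0.05")
  expect_true(file.exists(file.path(bundle, "landcover.asc")))

  pts <- file.path(wd, "points.csv")
  cli("sample", "--landscape", bundle, "--n", "400", "--seed", "4",
      "--out", pts)
  expect_true(file.exists(pts))

  cli("variogram", "--points", pts, "--out", file.path(wd, "vg.csv"),
      "--fit-out", file.path(wd, "vgfit.json"), "--max-lag", "150",
      "--lag-width", "15")
  expect_true(file.exists(file.path(wd, "vg.csv")))

  series <- data.frame(plot_id = rep(c("a", "b"), each = 20),
                       year = rep(2000:2019, 2),
                       value = c(40 + 0.3 * (0:19), rep(50, 20)))
  write.csv(series, file.path(wd, "series.csv"), row.names = FALSE)
  cli("trend", "--table", file.path(wd, "series.csv"),
      "--out", file.path(wd, "trends.csv"))
  tr <- read.csv(file.path(wd, "trends.csv"))
  expect_equal(tr$slope_abs[tr$plot_id == "a"], 0.3, tolerance = 1e-8)

  out <- file.path(wd, "run")
  cli("run-all", "--out", out, "--seed", "5", "--spacing-km", "60",
      "--lon-min", "-105", "--lon-max", "-103",
      "--lat-min", "52", "--lat-max", "63", "--res", "0.05")
  expect_true(file.exists(file.path(out, "plots.csv")))
  expect_true(file.exists(file.path(out, "profile.csv")))
  expect_true(file.exists(file.path(out, "log.txt")))

  cli("summarize", "--plots", file.path(out, "plots.csv"),
      "--out", file.path(wd, "summ"))
  expect_true(file.exists(file.path(wd, "summ", "strata_zone.csv")))

  cli("fit", "--plots", file.path(out, "plots.csv"),
      "--out", file.path(wd, "curves.csv"), "--correlation", "none")
  expect_true(file.exists(file.path(wd, "curves.csv")))
  unlink(wd, recursive = TRUE)
})
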