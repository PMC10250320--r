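make_profile_data <- function(n = 300, strata = c("undisturbed", "fire"),
                              offset = c(0, -0.2), noise = 0.02,
                              f = function(x) 0.1 * x, seed = 61) {
  set.seed(seed)
  sbd <- runif(n, -1.5, 1.5)
  stratum <- sample(strata, n, replace = TRUE)
  y <- f(sbd) + offset[match(stratum, strata)] + rnorm(n, 0, noise)
  data.frame(slope_abs = y, sbd = sbd, disturbance_category = stratum,
             lon = runif(n, -108, -104), lat = runif(n, 52, 62),
             transect_id = sample(1:6, n, replace = TRUE))
}

test_that("noiseless linear responses are reproduced per stratum", {
  d <- make_profile_data(noise = 1e-8)
  fit <- fit_smooth_by_stratum(d, "slope_abs", "sbd",
                               correlation = "none",
                               random_transect = FALSE)
  cv <- fit$curves
  truth <- 0.1 * cv$x + ifelse(cv$stratum == "fire", -0.2, 0)
  expect_lt(max(abs(cv$fit - truth)), 1e-3)
  expect_true(all(cv$se >= 0))
  expect_lt(max(cv$se), 1e-3)  # SE collapses as noise vanishes
})

test_that("a constant offset between strata is preserved in the curves", {
  d <- make_profile_data(noise = 0.01,
                         f = function(x) 0.15 * sin(2 * x), seed = 62)
  fit <- fit_smooth_by_stratum(d, "slope_abs", "sbd",
                               correlation = "none",
                               random_transect = FALSE)
  cv <- fit$curves
  gap <- cv$fit[cv$stratum == "fire"] - cv$fit[cv$stratum == "undisturbed"]
  expect_lt(max(abs(gap + 0.2)), 0.03)
})

test_that("adding a constant to the response shifts all curves by it", {
  d <- make_profile_data(seed = 63)
  f1 <- fit_smooth_by_stratum(d, "slope_abs", "sbd", correlation = "none",
                              random_transect = FALSE)
  d2 <- d
  d2$slope_abs <- d2$slope_abs + 1.25
  f2 <- fit_smooth_by_stratum(d2, "slope_abs", "sbd",
                              correlation = "none",
                              random_transect = FALSE)
  expect_equal(f2$curves$fit, f1$curves$fit + 1.25, tolerance = 1e-6)
})

test_that("humpback signal is recovered under correlated residuals", {
  hump <- function(x) 0.25 * exp(-((x - 0.3)^2) / 0.3) - 0.1
  set.seed(64)
  n <- 350
  base <- make_profile_data(n = n, strata = "all", offset = 0,
                            noise = 0, f = hump, seed = 64)
  corr <- simulate_exp_points(n, c(-108, -104), c(52, 62), 90, 0.04,
                              seed = 65, nugget_sd = 0.02)
  base$slope_abs <- base$slope_abs + corr$value
  base$lon <- corr$lon
  base$lat <- corr$lat
  fit <- fit_smooth_by_stratum(base, "slope_abs", "sbd", stratum = NULL,
                               correlation = "exponential",
                               range_init = 90)
  rmse <- sqrt(mean((fit$curves$fit - hump(fit$curves$x))^2))
  expect_lt(rmse, 0.05)
})

test_that("single-predictor models rank informative predictors and flag degenerates", {
  set.seed(66)
  n <- 250
  d <- data.frame(
    mat = runif(n, -3, 3), map = runif(n, 300, 600),
    constant = 5,
    lon = runif(n, -108, -104), lat = runif(n, 52, 62),
    transect_id = sample(1:5, n, TRUE),
    disturbance_category = "undisturbed"
  )
  d$slope_abs <- 0.1 * d$mat + rnorm(n, 0, 0.05)
  fits <- fit_single_predictor_models(
    d, c("mat", "map", "constant"), response = "slope_abs",
    stratum = NULL, correlation = "none", random_transect = FALSE)
  expect_length(fits, 3L)
  expect_true(fits$constant$degenerate)
  expect_gt(fits$mat$r_sq, fits$map$r_sq)

  single <- fit_single_predictor_models(d, "mat", response = "slope_abs",
                                        stratum = NULL,
                                        correlation = "none",
                                        random_transect = FALSE)
  expect_length(single, 1L)
})

test_that("small strata are dropped with a warning", {
  d <- make_profile_data(n = 120, seed = 67)
  d$disturbance_category[1:3] <- "rare"
  expect_warning(
    fit <- fit_smooth_by_stratum(d, "slope_abs", "sbd",
                                 correlation = "none",
                                 random_transect = FALSE),
    "dropping strata")
  expect_false("rare" %in% fit$curves$stratum)
})

test_that("collinearity screen flags duplicated and negated columns", {
  set.seed(68)
  d <- data.frame(a = rnorm(200))
  d$b <- d$a
  d$c <- -d$a
  d$ind <- rnorm(200)
  sc <- collinearity_screen(d, c("a", "b", "c", "ind"))
  expect_equal(sc$correlation["a", "b"], 1)
  expect_equal(sc$correlation["a", "c"], -1)
  expect_true(any(sc$flagged$var1 == "a" & sc$flagged$var2 == "b"))
  expect_lt(abs(sc$correlation["a", "ind"]), 0.2)
  # independent columns at n = 10000 are near-orthogonal
  set.seed(69)
  big <- data.frame(x = rnorm(10000), y = rnorm(10000))
  expect_lt(abs(collinearity_screen(big, c("x", "y"))$correlation["x", "y"]),
            0.05)
})
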