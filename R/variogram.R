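# Spatial structure of trend fields: random point sampling, empirical
# semivariogram with great-circle lags, weighted least-squares model fits
# (exponential / Gaussian / spherical / nugget-only) and selection of a
# residual correlation structure by information criterion. The fitted
# practical range sets the minimum spacing between sampling transects.

#' Sample random valid locations with their values
#'
#' Uniform sampling without replacement from the non-missing cells of a grid,
#' or from the rows of a point/plot table.
#'
#' @param field A [bt_grid()] or a `data.frame` with columns `lon`, `lat` and
#'   a value column.
#' @param n Number of points to draw; must not exceed the number of valid
#'   cells/rows.
#' @param seed Integer seed; identical seeds reproduce identical point sets.
#' @param value Name of the value column when `field` is a `data.frame`.
#' @return A `data.frame` with columns `lon`, `lat`, `value`.
#' @export
sample_random_points <- function(field, n, seed, value = "value") {
  stopifnot(n >= 0, n == round(n))
  if (inherits(field, "bt_grid")) {
    valid <- which(!is.na(field$values))
    if (n > length(valid)) {
      stop("requested ", n, " points but only ", length(valid),
           " valid cells")
    }
    set.seed(seed)
    take <- if (n == 0L) integer(0) else valid[sample.int(length(valid), n)]
    ij <- arrayInd(take, dim(field$values))
    ctr <- grid_centers(field)
    data.frame(lon = ctr$lon[ij[, 2L]], lat = ctr$lat[ij[, 1L]],
               value = field$values[take])
  } else {
    stopifnot(is.data.frame(field),
              all(c("lon", "lat", value) %in% names(field)))
    ok <- which(!is.na(field[[value]]))
    if (n > length(ok)) {
      stop("requested ", n, " points but only ", length(ok), " valid rows")
    }
    set.seed(seed)
    take <- if (n == 0L) integer(0) else ok[sample.int(length(ok), n)]
    data.frame(lon = field$lon[take], lat = field$lat[take],
               value = field[[value]][take])
  }
}

#' Empirical semivariogram
#'
#' Bins all point pairs by great-circle distance and computes
#' `gamma(h) = sum((z_i - z_j)^2) / (2 N_h)` per lag bin. Pairs are
#' accumulated in row blocks so that no full distance matrix is formed.
#'
#' @param points `data.frame` with columns `lon`, `lat`, `value`.
#' @param lag_width_km Bin width in km (default 25).
#' @param max_lag_km Largest lag considered (default 500).
#' @return A `data.frame` of class `bt_variogram` with columns `lag_center`
#'   (km), `semivariance` (`NA` for empty bins) and `n_pairs`.
#' @export
empirical_variogram <- function(points, lag_width_km = 25,
                                max_lag_km = 500) {
  stopifnot(all(c("lon", "lat", "value") %in% names(points)),
            lag_width_km > 0, max_lag_km > lag_width_km)
  pts <- points[!is.na(points$value), , drop = FALSE]
  n <- nrow(pts)
  if (n < 2L) {
    stop("empirical_variogram() needs at least 2 valued points")
  }
  nbins <- ceiling(max_lag_km / lag_width_km)
  counts <- numeric(nbins)
  sums <- numeric(nbins)
  block <- 256L
  for (i0 in seq(1L, n - 1L, by = block)) {
    i1 <- min(i0 + block - 1L, n - 1L)
    for (i in i0:i1) {
      j <- (i + 1L):n
      d <- haversine_km(pts$lon[i], pts$lat[i], pts$lon[j], pts$lat[j])
      b <- ceiling(d / lag_width_km)
      keep <- b >= 1L & b <= nbins
      if (!any(keep)) next
      dz2 <- (pts$value[i] - pts$value[j][keep])^2
      counts <- counts + tabulate(b[keep], nbins)
      sums <- sums + unname(tapply(dz2, factor(b[keep], levels = 1:nbins),
                                   sum, default = 0))
    }
  }
  out <- data.frame(
    lag_center = (seq_len(nbins) - 0.5) * lag_width_km,
    semivariance = ifelse(counts > 0, sums / (2 * counts), NA_real_),
    n_pairs = as.integer(counts)
  )
  class(out) <- c("bt_variogram", "data.frame")
  out
}

variogram_curve <- function(model, h, c0, c, a) {
  c0 + c * switch(model,
    exponential = 1 - exp(-h / a),
    gaussian = 1 - exp(-(h / a)^2),
    spherical = ifelse(h < a, 1.5 * h / a - 0.5 * (h / a)^3, 1),
    nugget = ifelse(h > 0, 1, 1)
  )
}

practical_range_of <- function(model, a) {
  switch(model,
    exponential = 3 * a,
    gaussian = sqrt(3) * a,
    spherical = a,
    nugget = NA_real_
  )
}

#' Fit a variogram model by weighted least squares
#'
#' Fits nugget `c0`, partial sill `c` and range parameter `a` to an empirical
#' variogram, weighting residuals by pair counts. The practical range is the
#' distance at which the model reaches 95% of its sill (`3a` for the
#' exponential, `sqrt(3) a` for the Gaussian, `a` for the spherical model).
#' When the fitted partial sill is negligible relative to the total sill the
#' range is not identifiable and is flagged `NA`.
#'
#' @param vg A [empirical_variogram()] result (or any `data.frame` with
#'   columns `lag_center`, `semivariance`, `n_pairs`).
#' @param model One of `"exponential"`, `"gaussian"`, `"spherical"`,
#'   `"nugget"`.
#' @return A list of class `bt_variogram_fit`: `model`, `nugget`,
#'   `partial_sill`, `range_param`, `practical_range`, `wrss`, `converged`,
#'   `identifiable`.
#' @export
fit_variogram_model <- function(vg, model = c("exponential", "gaussian",
                                              "spherical", "nugget")) {
  model <- match.arg(model)
  d <- vg[!is.na(vg$semivariance) & vg$n_pairs > 0, , drop = FALSE]
  if (nrow(d) < 4L) {
    stop("fit_variogram_model() needs at least 4 populated lags")
  }
  h <- d$lag_center
  g <- d$semivariance
  w <- d$n_pairs
  sill0 <- mean(g[h >= stats::quantile(h, 0.5)])
  c00 <- max(min(g), 1e-10)
  if (model == "nugget") {
    c0 <- sum(w * g) / sum(w)
    fit <- list(c0 = c0, c = 0, a = NA_real_,
                wrss = sum(w * (g - c0)^2), converged = TRUE)
  } else {
    starts <- expand.grid(a = max(h) * c(0.05, 0.15, 0.4),
                          f = c(0.25, 0.75))
    best <- NULL
    for (k in seq_len(nrow(starts))) {
      st <- list(c0 = c00 * starts$f[k] + 1e-10,
                 c = max(sill0 - c00 * starts$f[k], 1e-8),
                 a = starts$a[k])
      res <- tryCatch(
        minpack.lm::nlsLM(
          g ~ variogram_curve(model, h, c0, c, a),
          start = st, weights = w,
          lower = c(c0 = 0, c = 0, a = 1e-6),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (!is.null(res)) {
        wrss <- sum(w * stats::residuals(res)^2)
        if (is.null(best) || wrss < best$wrss) {
          p <- stats::coef(res)
          best <- list(c0 = unname(p["c0"]), c = unname(p["c"]),
                       a = unname(p["a"]), wrss = wrss, converged = TRUE)
        }
      }
    }
    # non-convergence (e.g. pure-nugget data): report the flat fit, flagged
    c0 <- sum(w * g) / sum(w)
    fit <- best %||% list(c0 = c0, c = 0, a = NA_real_,
                          wrss = sum(w * (g - c0)^2), converged = FALSE)
  }
  # the range is identifiable only when the partial sill is a real share of
  # the total sill and the fitted plateau is reached within the observed
  # lags (otherwise the variances never level off in the data)
  pr_raw <- if (is.na(fit$a)) NA_real_ else practical_range_of(model, fit$a)
  identifiable <- isTRUE(fit$converged) && !is.na(fit$c) &&
    fit$c > 0.05 * (fit$c0 + fit$c) && model != "nugget" &&
    !is.na(pr_raw) && pr_raw <= 2 * max(h)
  structure(list(
    model = model, nugget = fit$c0, partial_sill = fit$c,
    range_param = fit$a,
    practical_range = if (identifiable) practical_range_of(model, fit$a)
                      else NA_real_,
    wrss = fit$wrss, converged = isTRUE(fit$converged),
    identifiable = identifiable
  ), class = "bt_variogram_fit")
}

#' @export
print.bt_variogram_fit <- function(x, ...) {
  cat(sprintf(
    "<bt_variogram_fit> %s: nugget %.4g, partial sill %.4g, range %.4g\n",
    x$model, x$nugget, x$partial_sill, x$range_param))
  cat(sprintf("  practical range: %s km (%s)\n",
              format(x$practical_range, digits = 4),
              if (x$identifiable) "identifiable" else "not identifiable"))
  invisible(x)
}

#' Predicted semivariance from a fitted model
#'
#' @param object A [fit_variogram_model()] result.
#' @param h Lags in km.
#' @param ... Ignored.
#' @return Semivariances at `h`.
#' @export
predict.bt_variogram_fit <- function(object, h, ...) {
  variogram_curve(object$model, h, object$nugget, object$partial_sill,
                  if (is.na(object$range_param)) 1 else object$range_param)
}

#' Choose a residual spatial correlation structure
#'
#' Fits an intercept-only generalized least-squares model under each
#' candidate residual-correlation family (none, exponential, Gaussian,
#' spherical, with a nugget) and returns the candidate minimizing the
#' small-sample-corrected information criterion (AICc). Non-converging or
#' singular candidates are dropped with a warning.
#'
#' @param points `data.frame` with columns `lon`, `lat`, `value`.
#' @param candidates Subset of `c("none", "exponential", "gaussian",
#'   "spherical")`.
#' @param max_points GLS cost grows with the cube of the point count, so
#'   larger sets are subsampled to this size (seeded). Default 400.
#' @param seed Seed for the subsample.
#' @return A list: `best` (model name), `table` (`data.frame` of candidate,
#'   logLik, df, AICc).
#' @export
select_correlation_structure <- function(points,
                                         candidates = c("none", "exponential",
                                                        "gaussian",
                                                        "spherical"),
                                         max_points = 400L, seed = 1L) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  pts <- points[!is.na(points$value), , drop = FALSE]
  if (nrow(pts) < 50L) {
    stop("select_correlation_structure() needs at least 50 points")
  }
  if (length(candidates) == 1L) {
    return(list(best = candidates,
                table = data.frame(candidate = candidates, logLik = NA_real_,
                                   df = NA_real_, AICc = NA_real_)))
  }
  if (nrow(pts) > max_points) {
    set.seed(seed)
    pts <- pts[sample.int(nrow(pts), max_points), , drop = FALSE]
  }
  km <- project_km(pts$lon, pts$lat)
  dat <- data.frame(value = pts$value, kx = km$x, ky = km$y)
  # tiny jitter guards corStruct against exactly duplicated locations
  dup <- duplicated(round(dat$kx, 6) * 1e6 + round(dat$ky, 6))
  if (any(dup)) {
    dat$kx[dup] <- dat$kx[dup] + stats::runif(sum(dup), -1e-3, 1e-3)
  }
  cor_of <- function(nm) {
    switch(nm,
      none = NULL,
      exponential = nlme::corExp(form = ~ kx + ky, nugget = TRUE),
      gaussian = nlme::corGaus(form = ~ kx + ky, nugget = TRUE),
      spherical = nlme::corSpher(form = ~ kx + ky, nugget = TRUE)
    )
  }
  rows <- lapply(candidates, function(nm) {
    fit <- tryCatch(
      nlme::gls(value ~ 1, data = dat, correlation = cor_of(nm),
                method = "ML",
                control = nlme::glsControl(maxIter = 100, msMaxIter = 100,
                                           returnObject = FALSE)),
      error = function(e) {
        warning("correlation candidate '", nm, "' failed to fit: ",
                conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (is.null(fit)) {
      return(data.frame(candidate = nm, logLik = NA_real_, df = NA_real_,
                        AICc = NA_real_))
    }
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    n <- nrow(dat)
    aicc <- -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    data.frame(candidate = nm, logLik = as.numeric(ll), df = k, AICc = aicc)
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$AICc))
  if (length(ok) == 0L) {
    stop("no correlation-structure candidate converged")
  }
  list(best = tab$candidate[ok[which.min(tab$AICc[ok])]], table = tab)
}
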