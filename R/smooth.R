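# Semiparametric profile models: penalized cubic splines of a predictor with
# per-stratum interaction smooths, transect random intercepts and an
# exponentially decaying residual spatial correlation, fitted with mgcv.

#' Fit stratum-wise smooth profiles of a response
#'
#' Fits `response ~ stratum + s(predictor, by = stratum)` with cubic
#' penalized splines, optionally adding a random intercept per transect and
#' an exponential residual correlation over great-circle-projected
#' coordinates (via `mgcv::gamm`, which estimates the mixed model with
#' `nlme`). Smoothing penalties are selected by (RE)ML. Strata with fewer
#' than `min_per_stratum` complete cases are dropped with a warning.
#' Returns per-stratum fitted curves with standard errors on an evenly
#' spaced predictor grid.
#'
#' @param plots Plot table.
#' @param response,predictor Column names of the response and the smooth
#'   predictor.
#' @param stratum Column name of the interaction stratum (e.g. the
#'   disturbance category, or a disturbance x vegetation crossing); `NULL`
#'   fits a single common smooth.
#' @param k Spline basis dimension (default 10).
#' @param random_transect Add a random intercept per `transect_id`
#'   (default `TRUE` when the column exists and correlation or random
#'   effects are requested).
#' @param correlation `"exponential"` for an exponential residual
#'   correlation (with nugget) within transects, `"none"` for independent
#'   residuals.
#' @param range_init Optional initial correlation range in km, typically the
#'   practical range from [fit_variogram_model()]; profiled by the optimizer.
#' @param grid_n Number of grid points per stratum curve.
#' @param min_per_stratum Minimum complete cases per stratum (default 10).
#' @return A list of class `bt_fitted_profile`: `curves` (`data.frame` of
#'   `stratum`, `x`, `fit`, `se`), `model` (the fitted object), `edf`,
#'   `r_sq`, `diagnostics` (residual summaries), `dropped_strata`,
#'   `degenerate`.
#' @export
fit_smooth_by_stratum <- function(plots, response, predictor,
                                  stratum = "disturbance_category",
                                  k = 10,
                                  random_transect = TRUE,
                                  correlation = c("exponential", "none"),
                                  range_init = NULL,
                                  grid_n = 100L,
                                  min_per_stratum = 10L) {
  correlation <- match.arg(correlation)
  stopifnot(response %in% names(plots), predictor %in% names(plots))
  dat <- data.frame(y = plots[[response]], x = plots[[predictor]])
  if (!is.null(stratum)) {
    dat$stratum <- factor(plots[[stratum]])
  } else {
    dat$stratum <- factor("all")
  }
  has_transect <- "transect_id" %in% names(plots)
  if (has_transect) dat$transect_id <- factor(plots$transect_id)
  if (all(c("lon", "lat") %in% names(plots))) {
    km <- project_km(plots$lon, plots$lat)
    dat$kx <- km$x
    dat$ky <- km$y
  } else if (correlation != "none") {
    stop("correlation requires lon/lat columns")
  }
  dat <- dat[stats::complete.cases(dat[c("y", "x", "stratum")]), ,
             drop = FALSE]
  if (stats::sd(dat$x) == 0 || !is.finite(stats::sd(dat$x))) {
    return(structure(list(curves = NULL, model = NULL, degenerate = TRUE,
                          reason = "constant predictor"),
                     class = "bt_fitted_profile"))
  }
  sizes <- table(dat$stratum)
  drop <- names(sizes)[sizes < min_per_stratum]
  if (length(drop)) {
    warning("dropping strata below ", min_per_stratum, " plots: ",
            paste(drop, collapse = ", "), call. = FALSE)
    dat <- dat[!(dat$stratum %in% drop), , drop = FALSE]
  }
  dat$stratum <- droplevels(dat$stratum)
  if (nrow(dat) < min_per_stratum || nlevels(dat$stratum) == 0L) {
    stop("no stratum large enough to fit")
  }
  k_eff <- max(4L, min(k, floor(min(table(dat$stratum)) * 0.9)))
  single <- nlevels(dat$stratum) == 1L
  fml <- if (single) {
    stats::as.formula(sprintf("y ~ s(x, k = %d, bs = 'cr')", k_eff))
  } else {
    stats::as.formula(
      sprintf("y ~ stratum + s(x, by = stratum, k = %d, bs = 'cr')", k_eff))
  }
  use_mixed <- correlation == "exponential" ||
    (random_transect && has_transect)
  model <- NULL
  gam_part <- NULL
  if (use_mixed) {
    corr <- NULL
    if (correlation == "exponential") {
      init <- if (!is.null(range_init) && is.finite(range_init)) {
        c(range_init / 3, 0.1)  # corExp range parameter ~ practical/3
      } else {
        NULL
      }
      form <- if (random_transect && has_transect) {
        ~ kx + ky | transect_id
      } else {
        ~ kx + ky
      }
      corr <- if (is.null(init)) {
        nlme::corExp(form = form, nugget = TRUE)
      } else {
        nlme::corExp(value = init, form = form, nugget = TRUE)
      }
    }
    rnd <- if (random_transect && has_transect) {
      list(transect_id = ~ 1)
    } else {
      NULL
    }
    model <- tryCatch(
      mgcv::gamm(fml, data = dat, random = rnd, correlation = corr,
                 method = "REML"),
      error = function(e) {
        warning("mixed smooth fit failed (", conditionMessage(e),
                "); refitting without correlation/random effects",
                call. = FALSE)
        NULL
      }
    )
    if (!is.null(model)) gam_part <- model$gam
  }
  if (is.null(gam_part)) {
    gam_part <- mgcv::gam(fml, data = dat, method = "REML")
    model <- gam_part
  }
  xr <- range(dat$x)
  curves <- do.call(rbind, lapply(levels(dat$stratum), function(s) {
    nd <- data.frame(x = seq(xr[1], xr[2], length.out = grid_n),
                     stratum = factor(s, levels = levels(dat$stratum)))
    pr <- mgcv::predict.gam(gam_part, newdata = nd, se.fit = TRUE)
    data.frame(stratum = s, x = nd$x, fit = as.numeric(pr$fit),
               se = as.numeric(pr$se.fit))
  }))
  resid <- stats::residuals(gam_part)
  structure(list(
    curves = curves,
    model = model,
    edf = sum(gam_part$edf),
    r_sq = summary(gam_part)$r.sq,
    diagnostics = list(
      resid_mean = mean(resid), resid_sd = stats::sd(resid),
      shapiro_p = if (length(resid) >= 10 && length(resid) <= 4999) {
        stats::shapiro.test(resid)$p.value
      } else {
        NA_real_
      },
      fitted_obs_cor = stats::cor(stats::fitted(gam_part), dat$y)
    ),
    dropped_strata = drop,
    degenerate = FALSE
  ), class = "bt_fitted_profile")
}

#' @export
print.bt_fitted_profile <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<bt_fitted_profile> degenerate fit:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("<bt_fitted_profile> %d strata, edf %.1f, r^2 %.3f\n",
              length(unique(x$curves$stratum)), x$edf, x$r_sq))
  invisible(x)
}

#' One smooth model per explanatory variable
#'
#' Explanatory variables for boreal tree-cover change are strongly
#' collinear, so instead of one joint model a separate smooth model is
#' fitted per predictor, each with the same stratum interaction, random
#' effects and residual correlation settings.
#'
#' @param plots Plot table.
#' @param predictors Character vector of predictor column names.
#' @param ... Passed to [fit_smooth_by_stratum()].
#' @inheritParams fit_smooth_by_stratum
#' @return Named list of `bt_fitted_profile` objects (degenerate entries for
#'   constant predictors).
#' @export
fit_single_predictor_models <- function(plots, predictors,
                                        response = "slope_abs", ...) {
  stopifnot(all(predictors %in% names(plots)))
  out <- lapply(predictors, function(p) {
    fit_smooth_by_stratum(plots, response = response, predictor = p, ...)
  })
  names(out) <- predictors
  out
}

#' Pairwise correlation screen of explanatory variables
#'
#' Reports the pairwise Pearson correlation matrix of the chosen fields
#' (pairwise-complete) and flags pairs whose absolute correlation exceeds a
#' threshold — a light-weight collinearity check run before single-predictor
#' modelling.
#'
#' @param plots Plot table.
#' @param fields Character vector of >= 2 numeric column names.
#' @param threshold Absolute correlation above which a pair is flagged
#'   (default 0.7).
#' @return A list: `correlation` (matrix), `flagged` (`data.frame` of
#'   `var1`, `var2`, `r`).
#' @export
collinearity_screen <- function(plots, fields, threshold = 0.7) {
  stopifnot(length(fields) >= 2L, all(fields %in% names(plots)))
  m <- as.matrix(plots[fields])
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  ij <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  flagged <- data.frame(
    var1 = rownames(cm)[ij[, 1L]],
    var2 = colnames(cm)[ij[, 2L]],
    r = cm[ij]
  )
  list(correlation = cm, flagged = flagged)
}
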