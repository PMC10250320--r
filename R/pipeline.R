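# End-to-end pipeline: landscape (simulated or loaded) -> random-point trend
# sample -> variogram and range -> transects at the fitted spacing -> plots,
# strata and SBD -> per-plot trends -> binned profiles, stratified summaries,
# range shrinkage, coarse trend map -> smooth profile models. Each stage logs
# its seed and counts so run tallies are auditable.

#' Pipeline run configuration
#'
#' @param landscape What to analyse: a [landscape_config()] (simulated at
#'   run time with a seed derived from `seed`), an already generated
#'   `bt_landscape`, or a directory path written by [write_landscape()].
#' @param seed Integer master seed; every stochastic stage derives its own
#'   seed from it.
#' @param n_variogram_points Random points for the trend variogram
#'   (default 10000).
#' @param lag_width_km,max_lag_km Variogram binning. The default caps lags
#'   at 200 km: transect spacing is about short-range sampling redundancy,
#'   and longer lags are dominated by the deterministic south-north profile
#'   rather than by residual autocorrelation.
#' @param spacing `"fitted"` (use the variogram's practical range, the
#'   default) or `"explicit"`.
#' @param spacing_km Transect spacing in km when `spacing = "explicit"`, and
#'   the fallback when a fitted range is not identifiable (default 133).
#' @param extension_plots Plots beyond each boundary (default 20).
#' @param cell Plot size in degrees (default 0.05).
#' @param bin_width Profile bin width in SBD units (default 0.025).
#' @param zone_map Passed to [assign_zone()].
#' @param shrinkage_threshold,shrinkage_epochs Treed-cover threshold
#'   (percent) and the two epoch year ranges for
#'   [range_shrinkage_metric()].
#' @param coarse_factor Block size for the coarse trend map (default 10).
#' @param stages Subset of `c("variogram", "summaries", "coarse_map",
#'   "smooth")`; plot building and per-plot trends always run.
#' @param smooth_stratum,smooth_response,smooth_correlation Settings of the
#'   smooth-model stage.
#' @param out_dir Optional output directory; when set, tables, the coarse
#'   map, the run log and the echoed configuration are written there.
#' @return A list of class `bt_pipeline_config`.
#' @export
pipeline_config <- function(landscape = landscape_config(),
                            seed = 1L,
                            n_variogram_points = 10000L,
                            lag_width_km = 25, max_lag_km = 200,
                            spacing = c("fitted", "explicit"),
                            spacing_km = 133,
                            extension_plots = 20L, cell = 0.05,
                            bin_width = 0.025,
                            zone_map = list(south = c(-1.1, -0.9),
                                            interior = c(-0.5, 0.5),
                                            north = c(0.5, 0.9)),
                            shrinkage_threshold = 10,
                            shrinkage_epochs = list(c(2000, 2004),
                                                    c(2015, 2019)),
                            coarse_factor = 10L,
                            stages = c("variogram", "summaries",
                                       "coarse_map", "smooth"),
                            smooth_stratum = "disturbance_category",
                            smooth_response = "slope_abs",
                            smooth_correlation = c("exponential", "none"),
                            out_dir = NULL) {
  spacing <- match.arg(spacing)
  smooth_correlation <- match.arg(smooth_correlation)
  structure(as.list(environment()), class = "bt_pipeline_config")
}

log_stage <- function(log, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(..., collapse = ""))
  c(log, msg)
}

#' Run the full trend-analysis pipeline
#'
#' Executes the stages configured in [pipeline_config()] and returns all
#' intermediate and final products. Any stage failure aborts with an error
#' naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `bt_run`: `landscape`, `variogram` (empirical
#'   table, model fit, correlation-structure selection), `spacing_km`,
#'   `transects`, `plots` (plot table with strata, covariates and trend
#'   columns), `cover` (plot x year matrix), `years`, `profile` (binned),
#'   `strata` (stratified summaries), `shrinkage`, `coarse_trend`
#'   ([bt_grid()] or `NULL`), `smooth` (`bt_fitted_profile` or `NULL`),
#'   `log` (character), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  log <- character(0)

  ## stage: landscape -------------------------------------------------------
  ls <- cfg$landscape
  if (is.character(ls)) {
    ls <- read_landscape(ls)
    log <- log_stage(log, "landscape", "loaded from directory")
  } else if (inherits(ls, "bt_landscape_config")) {
    ls$seed <- derive_seed(cfg$seed, "landscape")
    ls <- generate_landscape(ls)
    log <- log_stage(log, "landscape", "simulated with seed ",
                     ls$config$seed)
  } else if (!inherits(ls, "bt_landscape")) {
    stop("stage landscape: config$landscape must be a landscape, a ",
         "landscape config, or a bundle directory")
  }
  retained_mask <- bt_grid(
    ifelse(matrix(ls$landcover$values %in% LC_RETAINED,
                  nrow(ls$landcover$values)), 1, NA_real_),
    ls$landcover$lon0, ls$landcover$lat0, ls$landcover$res)

  ## stage: variogram -> transect spacing -----------------------------------
  vg <- NULL
  spacing_km <- cfg$spacing_km
  if ("variogram" %in% cfg$stages && cfg$spacing == "fitted") {
    pts <- sample_random_points(retained_mask, cfg$n_variogram_points,
                                derive_seed(cfg$seed, "points"))
    pts$value <- pixel_trends(ls$cover, pts$lon, pts$lat)
    pts <- pts[!is.na(pts$value), , drop = FALSE]
    emp <- empirical_variogram(pts, cfg$lag_width_km, cfg$max_lag_km)
    fit <- fit_variogram_model(emp, "exponential")
    sel <- tryCatch(
      select_correlation_structure(pts, seed = derive_seed(cfg$seed,
                                                           "select")),
      error = function(e) {
        warning("stage variogram: correlation selection failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    vg <- list(points = pts, empirical = emp, fit = fit, selection = sel)
    if (fit$identifiable && is.finite(fit$practical_range)) {
      spacing_km <- fit$practical_range
      log <- log_stage(log, "variogram", sprintf(
        "n=%d points, practical range %.1f km (%s correlation preferred)",
        nrow(pts), spacing_km, if (is.null(sel)) "?" else sel$best))
    } else {
      log <- log_stage(log, "variogram",
                       "range not identifiable; falling back to ",
                       cfg$spacing_km, " km spacing")
    }
  } else {
    log <- log_stage(log, "variogram", "skipped; explicit spacing ",
                     spacing_km, " km")
  }

  ## stage: sampling design --------------------------------------------------
  transects <- draw_transects(ls$boundaries, spacing_km,
                              derive_seed(cfg$seed, "transects"),
                              cell = cfg$cell)
  if (nrow(transects) == 0L) stop("stage transects: none could be placed")
  plots <- build_all_plots(transects, ls$boundaries,
                           extension_plots = cfg$extension_plots,
                           cell = cfg$cell)
  log <- log_stage(log, "transects", nrow(transects), " transects, ",
                   nrow(plots), " plots, spacing ",
                   sprintf("%.1f", spacing_km), " km")

  ## stage: aggregation, strata, covariates ----------------------------------
  nyr <- length(ls$cover$years)
  cover <- matrix(NA_real_, nrow(plots), nyr)
  veg <- character(nrow(plots))
  excl <- logical(nrow(plots))
  cat_ <- character(nrow(plots))
  dyear <- integer(nrow(plots))
  ffire <- numeric(nrow(plots))
  fharv <- numeric(nrow(plots))
  for (i in seq_len(nrow(plots))) {
    ag <- aggregate_plot(plots[i, ], ls$cover, ls$landcover)
    excl[i] <- ag$excluded
    veg[i] <- ag$vegetation_class
    if (!ag$excluded) cover[i, ] <- ag$series
    cd <- classify_disturbance(plots[i, ], ls$dist_type, ls$dist_year)
    cat_[i] <- cd$category
    dyear[i] <- if (is.na(cd$year)) NA_integer_ else cd$year
    ffire[i] <- cd$frac_fire
    fharv[i] <- cd$frac_harvest
  }
  plots$vegetation_class <- veg
  plots$excluded <- excl
  plots$disturbance_category <- cat_
  plots$disturbance_year <- dyear
  plots$frac_fire <- ffire
  plots$frac_harvest <- fharv
  plots <- attach_covariates(plots, ls$climate, ls$elevation)
  log <- log_stage(log, "plots", sum(!excl), " retained, ", sum(excl),
                   " excluded; disturbance: ",
                   paste(names(table(cat_)), table(cat_), sep = "=",
                         collapse = ", "))

  ## stage: per-plot trends ---------------------------------------------------
  trends <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    if (plots$excluded[i]) {
      trend_estimate_row(missing = TRUE, n_used = 0L)
    } else {
      estimate_trend(cover[i, ], ls$cover$years)
    }
  }))
  plots <- cbind(plots, trends)
  plots$zone <- assign_zone(plots$sbd, cfg$zone_map)
  log <- log_stage(log, "trends", sum(!plots$missing),
                   " plot trends estimated")

  ## stage: summaries ----------------------------------------------------------
  profile <- NULL
  strata <- NULL
  shrink <- NULL
  if ("summaries" %in% cfg$stages) {
    ok <- plots[!plots$missing, , drop = FALSE]
    profile <- binned_running_mean(ok, "slope_abs",
                                   bin_width = cfg$bin_width)
    strata <- list(
      disturbance = stratified_stats(ok, "slope_abs",
                                     "disturbance_category"),
      vegetation = stratified_stats(ok, "slope_abs", "vegetation_class"),
      zone = stratified_stats(ok[!is.na(ok$zone), ], "slope_abs", "zone"),
      disturbance_vegetation = stratified_stats(
        ok, "slope_abs", c("disturbance_category", "vegetation_class"))
    )
    shrink <- range_shrinkage_metric(
      plots[!plots$excluded, , drop = FALSE],
      cover[!plots$excluded, , drop = FALSE], ls$cover$years,
      threshold = cfg$shrinkage_threshold,
      epoch1 = cfg$shrinkage_epochs[[1]],
      epoch2 = cfg$shrinkage_epochs[[2]],
      bin_width = cfg$bin_width)
    log <- log_stage(log, "summaries", "profile bins ",
                     sum(profile$n > 0), "/", nrow(profile),
                     "; shrinkage ",
                     sprintf("%.4f", shrink$shrinkage))
  }

  ## stage: coarse trend map ---------------------------------------------------
  coarse <- NULL
  if ("coarse_map" %in% cfg$stages) {
    cs <- ls$cover
    cg <- lapply(seq_len(nyr), function(ti) {
      block_aggregate(bt_grid(cs$values[, , ti], cs$lon0, cs$lat0, cs$res),
                      cfg$coarse_factor)
    })
    vals <- vapply(seq_len(nrow(cg[[1]]$values) * ncol(cg[[1]]$values)),
                   function(k) {
                     series <- vapply(cg, function(g) g$values[k], 1)
                     if (sum(!is.na(series)) < 15L) return(NA_real_)
                     estimate_trend(series, cs$years)$slope_abs
                   }, 1)
    coarse <- bt_grid(matrix(vals, nrow(cg[[1]]$values)),
                      cg[[1]]$lon0, cg[[1]]$lat0, cg[[1]]$res)
    log <- log_stage(log, "coarse_map", "factor ", cfg$coarse_factor)
  }

  ## stage: smooth models -------------------------------------------------------
  smooth <- NULL
  if ("smooth" %in% cfg$stages) {
    ok <- plots[!plots$missing, , drop = FALSE]
    smooth <- tryCatch(
      fit_smooth_by_stratum(
        ok, response = cfg$smooth_response, predictor = "sbd",
        stratum = cfg$smooth_stratum,
        correlation = cfg$smooth_correlation,
        range_init = if (!is.null(vg) && vg$fit$identifiable) {
          vg$fit$practical_range
        } else {
          NULL
        }),
      error = function(e) stop("stage smooth: ", conditionMessage(e)))
    log <- log_stage(log, "smooth", "edf ", sprintf("%.1f", smooth$edf))
  }

  run <- structure(list(
    landscape = ls, variogram = vg, spacing_km = spacing_km,
    transects = transects, plots = plots, cover = cover,
    years = ls$cover$years, profile = profile, strata = strata,
    shrinkage = shrink, coarse_trend = coarse, smooth = smooth,
    log = log, config = cfg
  ), class = "bt_run")
  if (!is.null(cfg$out_dir)) {
    write_run(run, cfg$out_dir)
  }
  run
}

# Pre-whitened trend at individual raster pixels (used for the variogram
# point sample).
pixel_trends <- function(stack, lon, lat, min_years = 15L) {
  j <- floor((lon - stack$lon0) / stack$res) + 1L
  i <- floor((lat - stack$lat0) / stack$res) + 1L
  vapply(seq_along(lon), function(k) {
    series <- stack$values[i[k], j[k], ]
    if (sum(!is.na(series)) < min_years) return(NA_real_)
    estimate_trend(series, stack$years, min_years = min_years)$slope_abs
  }, 1)
}

#' @export
print.bt_run <- function(x, ...) {
  cat("<bt_run>\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes the plot table, plot-level cover series, binned profile,
#' stratified summaries, variogram table, fitted curves, the coarse trend
#' map, a JSON shrinkage summary, the run log and the echoed configuration.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_plot_table(run$plots, file.path(dir, "plots.csv"))
  series <- data.frame(
    plot_id = rep(run$plots$plot_id, length(run$years)),
    year = rep(run$years, each = nrow(run$cover)),
    value = as.vector(run$cover)
  )
  utils::write.csv(series[!is.na(series$value), ],
                   file.path(dir, "cover_series.csv"), row.names = FALSE)
  if (!is.null(run$profile)) {
    utils::write.csv(run$profile, file.path(dir, "profile.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$strata)) {
    for (nm in names(run$strata)) {
      utils::write.csv(run$strata[[nm]],
                       file.path(dir, paste0("strata_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(run$variogram)) {
    utils::write.csv(run$variogram$empirical,
                     file.path(dir, "variogram.csv"), row.names = FALSE)
    fit <- run$variogram$fit
    jsonlite::write_json(
      list(model = fit$model, nugget = fit$nugget,
           partial_sill = fit$partial_sill, range_param = fit$range_param,
           practical_range = fit$practical_range,
           identifiable = fit$identifiable),
      file.path(dir, "variogram_fit.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$shrinkage) && !isTRUE(run$shrinkage$flagged)) {
    jsonlite::write_json(
      run$shrinkage[c("shrinkage", "south_edge_shift",
                      "north_edge_shift")],
      file.path(dir, "shrinkage.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$coarse_trend)) {
    write_ascii_grid(run$coarse_trend, file.path(dir, "coarse_trend.asc"))
  }
  if (!is.null(run$smooth) && !isTRUE(run$smooth$degenerate)) {
    utils::write.csv(run$smooth$curves, file.path(dir, "curves.csv"),
                     row.names = FALSE)
  }
  writeLines(run$log, file.path(dir, "log.txt"))
  cfg <- run$config
  cfg$landscape <- NULL  # echoed separately via the landscape config
  cfg$out_dir <- NULL
  yaml::write_yaml(unclass(cfg), file.path(dir, "run_config.yaml"))
  invisible(dir)
}

#' Plot-table CSV round trip
#'
#' CSV writer/reader pair for plot tables, preserving numeric values to full
#' double precision and category labels exactly.
#'
#' @param plots Plot table (`data.frame`).
#' @param path CSV path.
#' @return `read_plot_table()` returns the `data.frame`.
#' @export
write_plot_table <- function(plots, path) {
  utils::write.csv(format_df_full(plots), path, row.names = FALSE,
                   quote = TRUE, na = "")
  invisible(path)
}

format_df_full <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      v <- df[[nm]]
      df[[nm]] <- ifelse(is.na(v), NA_character_,
                         sprintf("%.17g", v))
    }
  }
  df
}

#' @rdname write_plot_table
#' @export
read_plot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if ("missing" %in% names(df)) df$missing <- as.logical(df$missing)
  if ("excluded" %in% names(df)) df$excluded <- as.logical(df$excluded)
  df
}
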