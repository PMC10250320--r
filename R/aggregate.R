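# Raster-to-plot aggregation with land-cover exclusion rules, disturbance
# classification, and climate/elevation covariates.

#' Land-cover class codes
#'
#' Integer codes used throughout the package. The six retained vegetation
#' types follow the condensed land-cover legend used for boreal plots;
#' classes from non-natural or unvegetated surfaces are excluded from plot
#' means and, where dominant, exclude the whole plot.
#'
#' @format Named integer vectors `LC_RETAINED` and `LC_EXCLUDED`.
#' @export
LC_RETAINED <- c(non_woody = 1L, shrubs = 2L, needleleaf = 3L, mixed = 4L,
                 broadleaf = 5L, unknown_forest = 6L)

#' @rdname LC_RETAINED
#' @export
LC_EXCLUDED <- c(water = 11L, urban = 12L, cropland = 13L, wetland = 14L,
                 bare = 15L, snow_ice = 16L)

#' Disturbance category labels
#'
#' The five mutually exclusive, exhaustive plot-level disturbance categories:
#' fire or harvest within the trend window (2000-2019), fire or harvest in
#' the preceding period (1985-1999), and plots undisturbed since 1985 (or
#' disturbed earlier).
#' @format Character vector of length 5.
#' @export
DISTURBANCE_CATEGORIES <- c("fire_2000_2019", "harvest_2000_2019",
                            "fire_1985_1999", "harvest_1985_1999",
                            "undisturbed")

# Pixel (row, col) index ranges of a plot footprint in a grid-aligned raster.
footprint_index <- function(grid_like, lon, lat, cell) {
  west <- lon - cell / 2
  south <- lat - cell / 2
  res <- grid_like$res
  j0 <- ceiling((west - grid_like$lon0) / res + 0.5 - 1e-9)
  i0 <- ceiling((south - grid_like$lat0) / res + 0.5 - 1e-9)
  nsub <- max(1L, round(cell / res))
  list(i = i0:(i0 + nsub - 1L), j = j0:(j0 + nsub - 1L))
}

clip_index <- function(ii, n) ii[ii >= 1L & ii <= n]

#' Aggregate one plot from a cover stack and a land-cover grid
#'
#' Computes the plot's annual tree-cover series as the mean over pixels whose
#' land-cover class is retained, and assigns the plot's vegetation class as
#' the modal class. A plot whose modal class is an excluded class (water,
#' urban, cropland, wetland, bare, snow/ice), or that contains no retained
#' pixel, is marked excluded and carries no series.
#'
#' @param plot One row of a plot table (needs `lon`, `lat`, `cell`).
#' @param cover_stack A [bt_stack()] of annual cover grids.
#' @param landcover A [bt_grid()] of integer class codes.
#' @return A list: `series` (numeric vector over `cover_stack$years`, or
#'   `NULL` when excluded), `vegetation_class` (name, or `"excluded"`),
#'   `excluded` (logical), `n_pixels`, `n_retained`.
#' @export
aggregate_plot <- function(plot, cover_stack, landcover) {
  fi <- footprint_index(landcover, plot$lon, plot$lat, plot$cell)
  i <- clip_index(fi$i, nrow(landcover$values))
  j <- clip_index(fi$j, ncol(landcover$values))
  if (!length(i) || !length(j)) {
    return(list(series = NULL, vegetation_class = "excluded",
                excluded = TRUE, n_pixels = 0L, n_retained = 0L))
  }
  classes <- as.vector(landcover$values[i, j, drop = FALSE])
  classes <- classes[!is.na(classes)]
  if (!length(classes)) {
    return(list(series = NULL, vegetation_class = "excluded",
                excluded = TRUE, n_pixels = 0L, n_retained = 0L))
  }
  tab <- table(classes)
  modal <- as.integer(names(tab)[which.max(tab)])
  retained_mask <- matrix(landcover$values[i, j, drop = FALSE] %in%
                            LC_RETAINED, nrow = length(i))
  n_ret <- sum(retained_mask)
  if (modal %in% LC_EXCLUDED || n_ret == 0L) {
    return(list(series = NULL, vegetation_class = "excluded",
                excluded = TRUE, n_pixels = length(classes),
                n_retained = n_ret))
  }
  veg <- names(LC_RETAINED)[match(modal, LC_RETAINED)]
  # cover stack shares the land-cover georeferencing
  sub <- cover_stack$values[i, j, , drop = FALSE]
  series <- apply(sub, 3L, function(m) mean(m[retained_mask], na.rm = TRUE))
  list(series = as.numeric(series), vegetation_class = veg, excluded = FALSE,
       n_pixels = length(classes), n_retained = n_ret)
}

#' Classify the disturbance history of one plot
#'
#' Computes the fractions of the plot footprint disturbed by wildfire and by
#' timber harvest, picks the type with the larger disturbed area (ties go to
#' fire), records the year of that type's largest-area event, and assigns one
#' of the five [DISTURBANCE_CATEGORIES]. Any sign of disturbance, however
#' small, classifies the plot as disturbed.
#'
#' @param plot One row of a plot table (needs `lon`, `lat`, `cell`).
#' @param dist_type A [bt_grid()]: 0 = none, 1 = fire, 2 = harvest.
#' @param dist_year A [bt_grid()] of disturbance years (NA where none).
#' @param window Trend window years, default `c(2000, 2019)`; earlier events
#'   back to 1985 fall in the pre-window categories.
#' @return A list: `category`, `year` (NA when undisturbed), `frac_fire`,
#'   `frac_harvest`.
#' @export
classify_disturbance <- function(plot, dist_type, dist_year,
                                 window = c(2000, 2019)) {
  fi <- footprint_index(dist_type, plot$lon, plot$lat, plot$cell)
  i <- clip_index(fi$i, nrow(dist_type$values))
  j <- clip_index(fi$j, ncol(dist_type$values))
  types <- as.vector(dist_type$values[i, j, drop = FALSE])
  years <- as.vector(dist_year$values[i, j, drop = FALSE])
  n <- sum(!is.na(types))
  if (n == 0L) {
    return(list(category = "undisturbed", year = NA_integer_,
                frac_fire = NA_real_, frac_harvest = NA_real_))
  }
  frac_fire <- sum(types == 1L, na.rm = TRUE) / n
  frac_harvest <- sum(types == 2L, na.rm = TRUE) / n
  if (frac_fire == 0 && frac_harvest == 0) {
    return(list(category = "undisturbed", year = NA_integer_,
                frac_fire = 0, frac_harvest = 0))
  }
  type <- if (frac_fire >= frac_harvest) 1L else 2L  # tie -> fire
  yrs <- years[!is.na(types) & types == type & !is.na(years)]
  ytab <- table(yrs)
  year <- as.integer(names(ytab)[which.max(ytab)])  # largest-area event
  period <- if (year >= window[1]) {
    paste0(window[1], "_", window[2])
  } else {
    "1985_1999"
  }
  category <- paste0(if (type == 1L) "fire_" else "harvest_", period)
  list(category = category, year = year, frac_fire = frac_fire,
       frac_harvest = frac_harvest)
}

#' Attach climate and elevation covariates to a plot table
#'
#' Looks up, for every plot, the nearest climate cell's annual mean
#' temperature and precipitation series, computes window means and
#' pre-whitened trends over the long (1980-2019) and short (2000-2019)
#' windows with [estimate_trend()], and the mean elevation over the plot
#' footprint.
#'
#' @param plots Plot table (`lon`, `lat`, `cell`).
#' @param climate A [bt_climate()] object.
#' @param elevation A [bt_grid()] of elevation in m.
#' @return `plots` with added columns `mat`, `map`, `mat_trend_long`,
#'   `mat_trend_short`, `map_trend_long`, `map_trend_short`, `elevation`.
#' @export
attach_covariates <- function(plots, climate, elevation) {
  yrs <- climate$years
  short <- yrs >= 2000 & yrs <= 2019
  min_long <- max(4L, ceiling(0.75 * length(yrs)))
  n <- nrow(plots)
  out <- matrix(NA_real_, n, 7)
  colnames(out) <- c("mat", "map", "mat_trend_long", "mat_trend_short",
                     "map_trend_long", "map_trend_short", "elevation")
  for (k in seq_len(n)) {
    ci <- which.min(abs(climate$lat - plots$lat[k]))
    cj <- which.min(abs(climate$lon - plots$lon[k]))
    mat <- climate$mat[ci, cj, ]
    map <- climate$map[ci, cj, ]
    tr <- function(v, w, min_years) {
      est <- estimate_trend(v[w], yrs[w], min_years = min_years)
      est$slope_abs
    }
    out[k, "mat"] <- mean(mat[short])
    out[k, "map"] <- mean(map[short])
    out[k, "mat_trend_long"] <- tr(mat, rep(TRUE, length(yrs)), min_long)
    out[k, "mat_trend_short"] <- tr(mat, short, 15L)
    out[k, "map_trend_long"] <- tr(map, rep(TRUE, length(yrs)), min_long)
    out[k, "map_trend_short"] <- tr(map, short, 15L)
    fi <- footprint_index(elevation, plots$lon[k], plots$lat[k],
                          plots$cell[k])
    i <- clip_index(fi$i, nrow(elevation$values))
    j <- clip_index(fi$j, ncol(elevation$values))
    if (length(i) && length(j)) {
      out[k, "elevation"] <- mean(elevation$values[i, j], na.rm = TRUE)
    }
  }
  cbind(plots, as.data.frame(out))
}

#' Annual climate series container
#'
#' @param lon,lat Cell-center coordinate vectors of the (coarse) climate
#'   grid.
#' @param years Calendar years of the annual series.
#' @param mat,map Arrays `[lat, lon, year]` of annual mean temperature (deg C)
#'   and annual precipitation (mm).
#' @return An object of class `bt_climate`.
#' @export
bt_climate <- function(lon, lat, years, mat, map) {
  stopifnot(identical(dim(mat), dim(map)),
            dim(mat)[1] == length(lat), dim(mat)[2] == length(lon),
            dim(mat)[3] == length(years))
  structure(list(lon = lon, lat = lat, years = years, mat = mat, map = map),
            class = "bt_climate")
}
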