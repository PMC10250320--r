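# South-north transect sampling design: random transect longitudes with a
# minimum great-circle spacing, contiguous 0.05-degree plots spanning the
# biome boundaries with fixed-length extensions, and the standardized
# boundary-distance (SBD) coordinate that maps the southern boundary to -1,
# the northern to +1 and extensions up to +/-1.5.

#' Draw random south-north transects with minimum spacing
#'
#' Longitudes are drawn uniformly over the shared extent of both boundary
#' lines and accepted greedily while every pairwise great-circle distance,
#' evaluated at the mid-domain latitude, stays at or above `min_spacing_km`.
#' The spacing is typically the practical range of the trend variogram, so
#' that transects are approximately independent. Candidate longitudes are
#' snapped to the 0.05-degree plot lattice.
#'
#' @param boundaries A [bt_boundaries()].
#' @param min_spacing_km Minimum allowed spacing in km (> 0).
#' @param seed Integer seed; identical seeds give identical transects.
#' @param cell Plot cell size in degrees (default 0.05).
#' @param max_failures Stop after this many consecutive rejected candidates.
#' @return A `data.frame` with columns `transect_id`, `lon`, ordered by
#'   longitude.
#' @export
draw_transects <- function(boundaries, min_spacing_km, seed, cell = 0.05,
                           max_failures = 500L) {
  stopifnot(min_spacing_km > 0)
  rng <- boundary_lon_range(boundaries)
  if (diff(rng) <= cell) {
    stop("longitudinal domain too narrow for a transect")
  }
  lat_mid <- mean(c(
    mean(boundary_lat(boundaries, "southern", seq(rng[1], rng[2],
                                                  length.out = 21))),
    mean(boundary_lat(boundaries, "northern", seq(rng[1], rng[2],
                                                  length.out = 21)))
  ))
  set.seed(seed)
  accepted <- numeric(0)
  failures <- 0L
  while (failures < max_failures) {
    cand <- stats::runif(1, rng[1], rng[2])
    cand <- (floor(cand / cell) + 0.5) * cell  # snap to plot lattice
    if (cand <= rng[1] || cand >= rng[2]) {
      failures <- failures + 1L
      next
    }
    if (length(accepted) &&
        (any(abs(accepted - cand) < cell / 2) ||
         any(haversine_km(accepted, lat_mid, cand, lat_mid) <
             min_spacing_km))) {
      failures <- failures + 1L
      next
    }
    accepted <- c(accepted, cand)
    failures <- 0L
  }
  accepted <- sort(accepted)
  data.frame(transect_id = seq_along(accepted), lon = accepted)
}

#' Standardized boundary distance for plot indices
#'
#' Interior plots between the two boundary-crossing plots are spaced linearly
#' by index, with the crossings at exactly -1 (south) and +1 (north).
#' Extension plots step outward by 0.025 per plot, so the 20th plot beyond a
#' boundary sits at exactly +/-1.5; values are capped there.
#'
#' @param idx Integer plot index along the transect (any origin, increasing
#'   northward).
#' @param south_idx,north_idx Indices of the plots containing the southern
#'   and northern boundary crossings; `north_idx > south_idx` required.
#' @param step Extension step per plot (default 0.025).
#' @return Numeric SBD values in `[-1.5, 1.5]`.
#' @export
standardize_boundary_distance <- function(idx, south_idx, north_idx,
                                          step = 0.025) {
  if (north_idx - south_idx < 1L) {
    stop("need at least 2 plots between the boundary crossings")
  }
  sbd <- ifelse(
    idx < south_idx, -1 - step * (south_idx - idx),
    ifelse(idx > north_idx, 1 + step * (idx - north_idx),
           -1 + 2 * (idx - south_idx) / (north_idx - south_idx))
  )
  pmax(pmin(sbd, 1.5), -1.5)
}

#' Build the plot stack of one transect
#'
#' Contiguous 0.05-degree plots covering the span between the two boundary
#' crossings, plus `extension_plots` plots beyond each boundary (roughly
#' 110 km at the default cell size). Plot cells are axis-aligned half-open
#' cells on the global 0.05-degree lattice; each plot record carries its
#' center coordinates and SBD.
#'
#' @param lon Transect longitude in degrees (snapped to the cell lattice).
#' @param boundaries A [bt_boundaries()].
#' @param transect_id Identifier stored with each plot.
#' @param extension_plots Number of plots beyond each boundary (default 20).
#' @param cell Plot size in degrees (default 0.05).
#' @return A `data.frame` with columns `plot_id`, `transect_id`, `lon`,
#'   `lat` (cell centers), `cell`, `sbd`, `position` (`"south_extension"`,
#'   `"interior"`, `"north_extension"`), ordered south to north.
#' @export
build_plots <- function(lon, boundaries, transect_id = 1L,
                        extension_plots = 20L, cell = 0.05) {
  lon <- (floor(lon / cell) + 0.5) * cell
  s_lat <- boundary_lat(boundaries, "southern", lon)
  n_lat <- boundary_lat(boundaries, "northern", lon)
  if (is.na(s_lat) || is.na(n_lat) || n_lat <= s_lat) {
    stop("transect at lon ", lon, " does not cross both boundaries")
  }
  s_idx <- floor(s_lat / cell)  # lattice index of the crossing plot
  n_idx <- floor(n_lat / cell)
  if (n_idx - s_idx < 1L) {
    stop("boundaries too close at lon ", lon, " for distinct crossing plots")
  }
  idx <- (s_idx - extension_plots):(n_idx + extension_plots)
  sbd <- standardize_boundary_distance(idx, s_idx, n_idx)
  pos <- ifelse(idx < s_idx, "south_extension",
                ifelse(idx > n_idx, "north_extension", "interior"))
  data.frame(
    plot_id = sprintf("t%03d_p%04d", transect_id, seq_along(idx)),
    transect_id = transect_id,
    lon = lon,
    lat = (idx + 0.5) * cell,
    cell = cell,
    sbd = sbd,
    position = pos
  )
}

#' Build plots for every transect in a set
#'
#' @param transects Output of [draw_transects()].
#' @param boundaries A [bt_boundaries()].
#' @inheritParams build_plots
#' @return Row-bound plot table for all transects.
#' @export
build_all_plots <- function(transects, boundaries, extension_plots = 20L,
                            cell = 0.05) {
  out <- lapply(seq_len(nrow(transects)), function(i) {
    build_plots(transects$lon[i], boundaries,
                transect_id = transects$transect_id[i],
                extension_plots = extension_plots, cell = cell)
  })
  do.call(rbind, out)
}
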