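# Biome boundary polylines: a southern and a northern line in geographic
# coordinates, with GeoJSON round-trip and latitude lookup by longitude.

#' Biome boundary pair
#'
#' @param southern,northern `data.frame`s with columns `lon`, `lat` tracing
#'   each boundary west to east. At every shared longitude the northern line
#'   must lie north of the southern one.
#' @return An object of class `bt_boundaries`.
#' @export
bt_boundaries <- function(southern, northern) {
  for (b in list(southern, northern)) {
    stopifnot(is.data.frame(b), all(c("lon", "lat") %in% names(b)),
              !is.unsorted(b$lon))
  }
  lon <- seq(max(min(southern$lon), min(northern$lon)),
             min(max(southern$lon), max(northern$lon)), length.out = 101)
  s <- stats::approx(southern$lon, southern$lat, lon)$y
  n <- stats::approx(northern$lon, northern$lat, lon)$y
  if (any(n <= s)) {
    stop("northern boundary must be north of the southern boundary ",
         "at every longitude")
  }
  structure(list(southern = southern, northern = northern),
            class = "bt_boundaries")
}

#' Boundary latitude at given longitudes
#'
#' Linear interpolation along the stored polyline.
#'
#' @param boundaries A [bt_boundaries()].
#' @param which `"southern"` or `"northern"`.
#' @param lon Longitudes in degrees.
#' @return Latitudes in degrees (`NA` outside the polyline's extent).
#' @export
boundary_lat <- function(boundaries, which = c("southern", "northern"), lon) {
  which <- match.arg(which)
  b <- boundaries[[which]]
  stats::approx(b$lon, b$lat, lon, rule = 1)$y
}

# Shared longitudinal extent of both boundary lines.
boundary_lon_range <- function(boundaries) {
  c(max(min(boundaries$southern$lon), min(boundaries$northern$lon)),
    min(max(boundaries$southern$lon), max(boundaries$northern$lon)))
}

#' Write boundaries as GeoJSON
#'
#' One `FeatureCollection` with two `LineString` features named `southern`
#' and `northern`, in WGS84 longitude/latitude order.
#'
#' @param boundaries A [bt_boundaries()].
#' @param path Output file path.
#' @export
write_boundaries_geojson <- function(boundaries, path) {
  feat <- function(name, df) {
    list(
      type = "Feature",
      properties = list(name = name),
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(df)),
                             function(i) c(df$lon[i], df$lat[i]))
      )
    )
  }
  fc <- list(type = "FeatureCollection",
             features = list(feat("southern", boundaries$southern),
                             feat("northern", boundaries$northern)))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read boundaries from GeoJSON
#'
#' @param path GeoJSON file with `LineString` features named `southern` and
#'   `northern`.
#' @return A [bt_boundaries()].
#' @export
read_boundaries_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection in ", path)
  }
  lines <- list()
  for (f in fc$features) {
    nm <- f$properties$name
    coords <- f$geometry$coordinates
    lines[[nm]] <- data.frame(
      lon = vapply(coords, function(p) as.numeric(p[[1L]]), 1),
      lat = vapply(coords, function(p) as.numeric(p[[2L]]), 1)
    )
  }
  if (!all(c("southern", "northern") %in% names(lines))) {
    stop("GeoJSON in ", path,
         " must contain features named 'southern' and 'northern'")
  }
  bt_boundaries(lines$southern, lines$northern)
}
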