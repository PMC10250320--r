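# Shared geodesy and small helpers.

KM_PER_DEG_LAT <- 110.574
KM_PER_DEG_LON_EQ <- 111.320

#' Great-circle distance in kilometres
#'
#' Haversine distance between paired points, via geosphere.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees; vectors are recycled
#'   rowwise.
#' @return Distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# Equirectangular projection to km, adequate for residual-correlation
# distances over a regional domain.
project_km <- function(lon, lat, lat_ref = mean(range(lat))) {
  list(
    x = lon * KM_PER_DEG_LON_EQ * cos(lat_ref * pi / 180),
    y = lat * KM_PER_DEG_LAT
  )
}

# Derive a reproducible sub-seed from a base seed and a stage label, kept
# within 32-bit integer range.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435 + offs) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
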