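# Minimal regular-grid raster container on geographic (WGS84) coordinates,
# with ESRI ASCII-grid text I/O and block aggregation. Rows run south to
# north (row 1 = southernmost), columns west to east.

#' Create a geographic grid
#'
#' @param values Numeric matrix; `values[i, j]` is the cell in the i-th row
#'   from the south and j-th column from the west.
#' @param lon0,lat0 Lower-left corner (degrees) of cell `[1, 1]`.
#' @param res Cell size in degrees (square cells).
#' @return An object of class `bt_grid`.
#' @export
bt_grid <- function(values, lon0, lat0, res) {
  stopifnot(is.matrix(values), res > 0)
  structure(list(values = values, lon0 = lon0, lat0 = lat0, res = res),
            class = "bt_grid")
}

#' @export
print.bt_grid <- function(x, ...) {
  cat(sprintf("<bt_grid> %d rows x %d cols at %g deg, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$res, x$lon0, x$lat0))
  cat(sprintf("  values: min %s, max %s, NA %d\n",
              format(suppressWarnings(min(x$values, na.rm = TRUE))),
              format(suppressWarnings(max(x$values, na.rm = TRUE))),
              sum(is.na(x$values))))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [bt_grid()].
#' @return List with numeric vectors `lon` (per column) and `lat` (per row).
#' @export
grid_centers <- function(grid) {
  list(
    lon = grid$lon0 + (seq_len(ncol(grid$values)) - 0.5) * grid$res,
    lat = grid$lat0 + (seq_len(nrow(grid$values)) - 0.5) * grid$res
  )
}

#' Look up grid values at point locations (nearest cell)
#'
#' @param grid A [bt_grid()].
#' @param lon,lat Point coordinates in degrees.
#' @return Numeric vector of cell values; `NA` outside the grid.
#' @export
grid_lookup <- function(grid, lon, lat) {
  j <- floor((lon - grid$lon0) / grid$res) + 1L
  i <- floor((lat - grid$lat0) / grid$res) + 1L
  ok <- i >= 1L & i <= nrow(grid$values) & j >= 1L & j <= ncol(grid$values)
  out <- rep(NA_real_, length(lon))
  out[ok] <- grid$values[cbind(i[ok], j[ok])]
  out
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text interchange format readable by standard GIS tools. Data rows
#' are written north to south as the format requires.
#'
#' @param grid A [bt_grid()].
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Value standing in for `NA` cells.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(grid$lon0, digits = 12)),
    paste("yllcorner", format(grid$lat0, digits = 12)),
    paste("cellsize", format(grid$res, digits = 12)),
    paste("NODATA_value", nodata)
  ), con)
  for (i in rev(seq_len(nrow(v)))) {
    writeLines(paste(format(v[i, ], digits = 10, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path File written by [write_ascii_grid()] or any conforming tool.
#' @return A [bt_grid()]; the nodata value becomes `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  k <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) == 2L &&
        tolower(parts[1L]) %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                                  "cellsize", "nodata_value")) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
      k <- k + 1L
    } else {
      break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path)
  }
  body <- lines[(k + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows) {
    stop("ASCII grid ", path, ": expected ", hdr$nrows, " data rows, got ",
         length(body))
  }
  rows <- lapply(body, function(ln) as.numeric(strsplit(trimws(ln),
                                                        "\\s+")[[1L]]))
  nc <- vapply(rows, length, 1L)
  if (any(nc != hdr$ncols)) {
    stop("ASCII grid ", path, ": row ", which(nc != hdr$ncols)[1L],
         " has wrong column count")
  }
  v <- do.call(rbind, rev(rows))  # back to south-first rows
  if (!is.null(hdr$nodata_value)) {
    v[v == hdr$nodata_value] <- NA_real_
  }
  bt_grid(v, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' Annual raster stack
#'
#' A grid time series sharing one georeference: `values[i, j, t]` is the
#' cell value in year `years[t]`.
#'
#' @param values Numeric array `[row, col, year]`.
#' @param years Calendar years, one per slice.
#' @inheritParams bt_grid
#' @return An object of class `bt_stack`.
#' @export
bt_stack <- function(values, years, lon0, lat0, res) {
  stopifnot(length(dim(values)) == 3L, dim(values)[3] == length(years),
            res > 0)
  structure(list(values = values, years = years, lon0 = lon0, lat0 = lat0,
                 res = res), class = "bt_stack")
}

#' Extract one year of a stack as a grid
#'
#' @param stack A [bt_stack()].
#' @param year Calendar year present in `stack$years`.
#' @return A [bt_grid()].
#' @export
stack_year <- function(stack, year) {
  t <- match(year, stack$years)
  if (is.na(t)) stop("year ", year, " not in stack")
  bt_grid(stack$values[, , t], stack$lon0, stack$lat0, stack$res)
}

#' Aggregate a grid into coarser blocks by averaging
#'
#' Missing-aware block means: each output cell is the mean of the non-missing
#' cells in its `factor` x `factor` block, or `NA` when the whole block is
#' missing. Trailing rows/columns that do not fill a block are dropped.
#'
#' @param grid A [bt_grid()].
#' @param factor Integer aggregation factor, >= 1.
#' @return A coarser [bt_grid()].
#' @export
block_aggregate <- function(grid, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  factor <- as.integer(factor)
  if (factor == 1L) {
    return(grid)
  }
  v <- grid$values
  ni <- nrow(v) %/% factor
  nj <- ncol(v) %/% factor
  stopifnot(ni >= 1L, nj >= 1L)
  v <- v[seq_len(ni * factor), seq_len(nj * factor), drop = FALSE]
  bi <- rep(seq_len(ni), each = factor)
  bj <- rep(seq_len(nj), each = factor)
  ok <- !is.na(v)
  vz <- ifelse(ok, v, 0)
  sums <- rowsum(t(rowsum(vz, bi)), bj)           # nj x ni
  counts <- rowsum(t(rowsum(ok + 0, bi)), bj)
  out <- t(sums / ifelse(counts == 0, NA_real_, counts))
  bt_grid(out, grid$lon0, grid$lat0, grid$res * factor)
}
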