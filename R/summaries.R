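# Descriptive profile summaries: binned means along the standardized
# boundary distance, stratified means by disturbance/vegetation/zone,
# coarse trend maps, and a range-shrinkage metric comparing the latitudinal
# span of treed area between two epochs.

#' Binned mean profile along standardized boundary distance
#'
#' Partitions `[-1.5, 1.5]` into half-open bins (leftmost closed) of width
#' `bin_width` and reports the mean, sample standard deviation and count of
#' the chosen value per bin.
#'
#' @param plots Plot table with an `sbd` column.
#' @param value Name of the value column (e.g. `"slope_abs"`).
#' @param bin_width Bin width in SBD units; the default 0.025 gives 120 bins.
#' @param range SBD interval to partition, default `c(-1.5, 1.5)`.
#' @return A `data.frame` with `bin_center`, `mean`, `sd`, `n`; bins without
#'   data have `n = 0` and missing moments.
#' @export
binned_running_mean <- function(plots, value, bin_width = 0.025,
                                range = c(-1.5, 1.5)) {
  stopifnot("sbd" %in% names(plots), value %in% names(plots))
  breaks <- seq(range[1], range[2], by = bin_width)
  nb <- length(breaks) - 1L
  v <- plots[[value]]
  ok <- !is.na(v) & !is.na(plots$sbd)
  # half-open [lo, hi), last bin closed on the right
  b <- findInterval(plots$sbd[ok], breaks, rightmost.closed = TRUE,
                    left.open = FALSE)
  keep <- b >= 1L & b <= nb
  b <- b[keep]
  v <- v[ok][keep]
  f <- factor(b, levels = seq_len(nb))
  n <- as.integer(table(f))
  data.frame(
    bin_center = (breaks[-length(breaks)] + breaks[-1L]) / 2,
    mean = as.numeric(tapply(v, f, mean, default = NA_real_)),
    sd = as.numeric(tapply(v, f, stats::sd, default = NA_real_)),
    n = n
  )
}

#' Assign latitudinal zones from SBD
#'
#' Maps standardized boundary distance into named zones. The defaults place
#' a southern-boundary zone at `(-1.1, -0.9]`, the biome interior at
#' `(-0.5, 0.5]` and a northern-interior zone at `(0.5, 0.9]`; SBD outside
#' every zone yields `NA`.
#'
#' @param sbd Numeric SBD values.
#' @param zone_map Named list of `c(lo, hi)` half-open intervals `(lo, hi]`.
#' @return Character zone labels (or `NA`).
#' @export
assign_zone <- function(sbd,
                        zone_map = list(south = c(-1.1, -0.9),
                                        interior = c(-0.5, 0.5),
                                        north = c(0.5, 0.9))) {
  out <- rep(NA_character_, length(sbd))
  for (nm in names(zone_map)) {
    z <- zone_map[[nm]]
    out[!is.na(sbd) & sbd > z[1] & sbd <= z[2]] <- nm
  }
  out
}

#' Stratified mean and standard deviation
#'
#' Mean, sample standard deviation (n - 1) and count of a value per stratum,
#' where strata are the crossing of the given grouping fields. Strata
#' present in the factor levels but empty in the data are reported with
#' `n = 0` and missing moments.
#'
#' @param plots Plot table.
#' @param value Value column name.
#' @param by Character vector of grouping column names.
#' @return A `data.frame`: one row per stratum with the grouping columns,
#'   `mean`, `sd`, `n`.
#' @export
stratified_stats <- function(plots, value, by) {
  stopifnot(value %in% names(plots), all(by %in% names(plots)))
  v <- plots[[value]]
  groups <- lapply(by, function(b) {
    v <- plots[[b]]
    if (is.factor(v)) v else factor(v)  # keep declared (possibly empty) levels
  })
  names(groups) <- by
  key <- interaction(groups, drop = FALSE, sep = "\r")
  ok <- !is.na(v) & !is.na(key)
  mean_by <- tapply(v[ok], droplevels(key[ok]), mean)
  sd_by <- tapply(v[ok], droplevels(key[ok]), stats::sd)
  n_by <- table(key[ok])
  labels <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  out <- as.data.frame(labels, stringsAsFactors = FALSE)
  names(out) <- by
  out$mean <- as.numeric(mean_by[levels(key)])
  out$sd <- as.numeric(sd_by[levels(key)])
  out$n <- as.integer(n_by[levels(key)])
  out$mean[out$n == 0L] <- NA_real_
  out$sd[out$n == 0L] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Coarsen a trend raster by block means
#'
#' Missing-aware mean aggregation of a trend map to a coarser resolution,
#' e.g. factor 4 to go from 250 m to about 1 km.
#'
#' @param trend A [bt_grid()] of per-pixel trends.
#' @param factor Integer aggregation factor >= 1.
#' @return A coarser [bt_grid()].
#' @export
coarse_trend_map <- function(trend, factor) {
  block_aggregate(trend, factor)
}

#' Range shrinkage of the treed distribution between two epochs
#'
#' Operationalizes "range shrinkage" as the contraction of the SBD span
#' occupied by treed plots: per epoch, plots are flagged treed when their
#' epoch-mean cover reaches `threshold`; the span is the distance between
#' the `probs` quantiles (default 5th and 95th) of the SBD values of treed
#' plots, and shrinkage is the first-epoch span minus the second-epoch span
#' (positive = contraction). Per-bin treed-area fractions are returned for
#' both epochs.
#'
#' @param plots Plot table with `sbd`.
#' @param cover Matrix of plot cover series, plots in rows, one column per
#'   year in `years`.
#' @param years Calendar years of the columns of `cover`.
#' @param threshold Cover percentage at or above which a plot counts as
#'   treed (default 10).
#' @param epoch1,epoch2 Year ranges `c(first, last)` of the two epochs.
#' @param probs Lower and upper quantiles defining the occupied span.
#' @param bin_width Bin width for the treed-fraction profiles.
#' @return A list of class `bt_range_shrinkage`: `shrinkage` (SBD units),
#'   `south_edge_shift`, `north_edge_shift` (positive = northward),
#'   `span` (per-epoch spans), `quantiles`, `profile` (per-bin treed
#'   fractions for both epochs), `n_treed`.
#' @export
range_shrinkage_metric <- function(plots, cover, years, threshold = 10,
                                   epoch1 = c(2000, 2004),
                                   epoch2 = c(2015, 2019),
                                   probs = c(0.05, 0.95),
                                   bin_width = 0.025) {
  stopifnot(nrow(cover) == nrow(plots), ncol(cover) == length(years))
  epoch_mean <- function(ep) {
    w <- years >= ep[1] & years <= ep[2]
    if (!any(w)) stop("epoch ", paste(ep, collapse = "-"),
                      " outside the cover years")
    rowMeans(cover[, w, drop = FALSE], na.rm = TRUE)
  }
  m1 <- epoch_mean(epoch1)
  m2 <- epoch_mean(epoch2)
  treed1 <- !is.na(m1) & m1 >= threshold
  treed2 <- !is.na(m2) & m2 >= threshold
  if (!any(treed1) || !any(treed2)) {
    return(structure(list(shrinkage = NA_real_, flagged = TRUE,
                          n_treed = c(sum(treed1), sum(treed2))),
                     class = "bt_range_shrinkage"))
  }
  q1 <- stats::quantile(plots$sbd[treed1], probs, names = FALSE)
  q2 <- stats::quantile(plots$sbd[treed2], probs, names = FALSE)
  frac_profile <- function(treed) {
    df <- plots
    df$treed <- as.numeric(treed)
    binned_running_mean(df, "treed", bin_width = bin_width)
  }
  structure(list(
    shrinkage = diff(q1) - diff(q2),
    south_edge_shift = q2[1] - q1[1],
    north_edge_shift = q2[2] - q1[2],
    span = c(epoch1 = diff(q1), epoch2 = diff(q2)),
    quantiles = rbind(epoch1 = q1, epoch2 = q2),
    profile = list(epoch1 = frac_profile(treed1),
                   epoch2 = frac_profile(treed2)),
    n_treed = c(epoch1 = sum(treed1), epoch2 = sum(treed2)),
    flagged = FALSE
  ), class = "bt_range_shrinkage")
}

#' @export
print.bt_range_shrinkage <- function(x, ...) {
  if (isTRUE(x$flagged)) {
    cat("<bt_range_shrinkage> flagged: no treed plots in an epoch\n")
  } else {
    cat(sprintf(
      "<bt_range_shrinkage> shrinkage %.4f (south edge %+.4f, north edge %+.4f)\n",
      x$shrinkage, x$south_edge_shift, x$north_edge_shift))
  }
  invisible(x)
}
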