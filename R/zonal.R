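#' @title Zonal statistics and raster-vector operations
#' @name zonal
NULL

#' Logical mask of raster cells inside a polygon
#'
#' A cell belongs to the zone when its center falls inside the polygon
#' (cell-center rule).
#'
#' @param r a [raster_grid()].
#' @param zone polygon [geometry()].
#' @return logical matrix of the raster's dimensions.
#' @export
cells_in_polygon <- function(r, zone) {
  cc <- cell_centers(r)
  # quick bounding-box prefilter
  bx <- range(zone$coords[, 1]); by <- range(zone$coords[, 2])
  colsel <- which(cc$x >= bx[1] - r$cellsize & cc$x <= bx[2] + r$cellsize)
  rowsel <- which(cc$y >= by[1] - r$cellsize & cc$y <= by[2] + r$cellsize)
  m <- matrix(FALSE, nrow(r$values), ncol(r$values))
  if (length(colsel) == 0L || length(rowsel) == 0L) return(m)
  xs <- rep(cc$x[colsel], each = length(rowsel))
  ys <- rep(cc$y[rowsel], times = length(colsel))
  inside <- point_in_polygon(xs, ys, zone)
  m[rowsel, colsel] <- inside
  m
}

#' Statistical mode with ties broken toward the lowest value
#' @param x numeric/integer vector (NAs removed).
#' @return the most frequent value; on ties, the smallest such value.
#' @export
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no values for mode")
  tab <- table(x)
  vals <- as.numeric(names(tab))
  min(vals[tab == max(tab)])
}

#' Zonal statistics of a raster within a polygon
#'
#' Summarises the valid (non-`NA`) cells whose centers fall inside the
#' zone polygon. `class_percentages` treats the raster as categorical and
#' returns the percent of valid cells per value (summing to 100).
#'
#' @param r a [raster_grid()].
#' @param zone polygon [geometry()].
#' @param stat one of `"max"`, `"mean"`, `"mode"`, `"percentiles"`,
#'   `"class_percentages"`.
#' @param probs percentile probabilities (for `stat = "percentiles"`).
#' @return a number, a named numeric vector (percentiles / class
#'   percentages).
#' @export
zonal_stats <- function(r, zone,
                        stat = c("max", "mean", "mode", "percentiles",
                                 "class_percentages"),
                        probs = c(0.25, 0.5, 0.75)) {
  stat <- match.arg(stat)
  vals <- zonal_values(r, zone)
  switch(stat,
         max  = max(vals),
         mean = mean(vals),
         mode = stat_mode(vals),
         percentiles = stats::quantile(vals, probs, type = 7),
         class_percentages = {
           tab <- table(vals)
           p <- 100 * as.numeric(tab) / length(vals)
           names(p) <- names(tab)
           p
         })
}

#' Valid raster values inside a zone
#' @inheritParams zonal_stats
#' @return numeric vector of in-zone non-`NA` cell values; errors (with a
#'   message naming the zone problem) when no valid cell falls inside.
#' @export
zonal_values <- function(r, zone) {
  m <- cells_in_polygon(r, zone)
  vals <- r$values[m]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    stop("zone contains no valid raster cells (empty zonal statistic)")
  vals
}

#' Percent of zone cells belonging to a set of class codes
#'
#' @param r categorical [raster_grid()] (e.g. land cover).
#' @param zone polygon [geometry()].
#' @param class_codes numeric vector of codes to count.
#' @return percent of valid in-zone cells with a code in `class_codes`.
#' @export
class_fraction <- function(r, zone, class_codes) {
  vals <- zonal_values(r, zone)
  100 * sum(vals %in% class_codes) / length(vals)
}

#' Nearest-point allocation surface
#'
#' Fills a raster from a point layer: each cell takes the numeric attribute
#' of its nearest point (ties go to the feature that comes first in the
#' layer). This is the allocation used to spread sampling-point values,
#' e.g. populations served by treatment plants, over the watershed.
#'
#' @param points a [vector_layer()] of point features.
#' @param attr name of the numeric attribute to spread.
#' @param template a [raster_grid()] providing the geometry of the output.
#' @param power if not `NULL`, inverse-distance weighting with this power
#'   is used instead of nearest-neighbour allocation.
#' @return a [raster_grid()].
#' @export
nearest_point_surface <- function(points, attr, template, power = NULL) {
  pts <- points$features
  if (length(pts) == 0L) stop("empty point set")
  xy <- t(vapply(pts, function(f) f$geometry$coords[1, ], numeric(2)))
  a <- vapply(pts, function(f) as.numeric(f$attributes[[attr]]), numeric(1))
  if (anyNA(a)) stop("attribute '", attr, "' missing on some points")
  cc <- cell_centers(template)
  nr <- length(cc$y); nc <- length(cc$x)
  out <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nc)) {
    dx2 <- (xy[, 1] - cc$x[j])^2
    for (i in seq_len(nr)) {
      d2 <- dx2 + (xy[, 2] - cc$y[i])^2
      if (is.null(power)) {
        out[i, j] <- a[which.min(d2)]   # which.min takes the first tie
      } else {
        if (any(d2 == 0)) out[i, j] <- a[which(d2 == 0)[1]]
        else {
          w <- 1 / d2^(power / 2)
          out[i, j] <- sum(w * a) / sum(w)
        }
      }
    }
  }
  raster_grid(out, template$xmin, template$ymin, template$cellsize,
              template$crs)
}

#' Cell-wise index surface
#'
#' Applies the aggregation equation per cell: the weighted sum of the seven
#' indicator grade rasters and the cell-wise hazard sum, plus their product
#' and the per-cell degradation state. Any `NA` input cell yields `NA`.
#'
#' @param grade_rasters named list of aligned [raster_grid()]s with names
#'   `W`, `R`, `A`, `a`, `S`, `T`, `I`, `C`.
#' @param weights a [wrastic_weights()] scheme.
#' @param hazard_rasters named list of aligned [raster_grid()]s with names
#'   `slope`, `aspect`, `permeability` (grade values).
#' @param type_rule a [hi_type_rule()].
#' @param thresholds see [class_thresholds()].
#' @return list of [raster_grid()]s: `wrastic` (weighted sum), `hi`
#'   (hazard sum), `wrastic_hi` (their product, the full aggregation
#'   equation) and `state` (1 = natural, 2 = semi-degraded, 3 = degraded).
#' @export
per_pixel_index <- function(grade_rasters, weights = wrastic_weights(),
                            hazard_rasters, type_rule = hi_type_rule(),
                            thresholds = class_thresholds()) {
  need_g <- .indicator_names
  need_h <- c("slope", "aspect", "permeability")
  if (!all(need_g %in% names(grade_rasters)))
    stop("missing indicator raster(s): ",
         paste(setdiff(need_g, names(grade_rasters)), collapse = ", "))
  if (!all(need_h %in% names(hazard_rasters)))
    stop("missing hazard raster(s): ",
         paste(setdiff(need_h, names(hazard_rasters)), collapse = ", "))
  ref <- grade_rasters[[need_g[1]]]
  for (r in c(grade_rasters[need_g], hazard_rasters[need_h]))
    if (!.rg_aligned(ref, r)) stop("input rasters are not aligned")

  wsum <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (nm in need_g)
    wsum <- wsum + as.integer(weights[[nm]]) * grade_rasters[[nm]]$values
  hi <- hazard_rasters$slope$values + hazard_rasters$aspect$values +
    hazard_rasters$permeability$values

  ok <- !is.na(wsum) & !is.na(hi)
  state <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  if (any(ok)) {
    ty <- assign_hi_type(as.integer(hi[ok]), type_rule)
    st <- classify_state(wsum[ok], ty, thresholds)
    state[ok] <- match(st, c("natural", "semi_degraded", "degraded"))
  }
  wsum[!ok] <- NA_real_
  hi2 <- hi; hi2[!ok] <- NA_real_
  mk <- function(v) raster_grid(v, ref$xmin, ref$ymin, ref$cellsize, ref$crs)
  list(wrastic = mk(wsum), hi = mk(hi2), wrastic_hi = mk(wsum * hi2),
       state = mk(state))
}
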