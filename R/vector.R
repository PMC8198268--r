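#' @title Vector geometries and spatial predicates
#' @name vector_layer
#' @description Minimal planar vector support: point/line/polygon features
#'   with flat attributes, shoelace areas, centroids, even-odd
#'   point-in-polygon, exact point/segment distances and distance-buffered
#'   selection. All coordinates are metres of a shared projected system.
NULL

#' Construct a geometry
#'
#' @param type `"point"`, `"line"` or `"polygon"`.
#' @param coords two-column matrix of (x, y) vertices; polygons need not
#'   repeat the first vertex.
#' @return object of class `geometry`.
#' @export
geometry <- function(type = c("point", "line", "polygon"), coords) {
  type <- match.arg(type)
  coords <- matrix(as.numeric(coords), ncol = 2)
  if (nrow(coords) == 0L) stop("geometry must have at least one vertex")
  if (type == "polygon") {
    if (nrow(coords) >= 2L &&
        all(coords[1, ] == coords[nrow(coords), ]))
      coords <- coords[-nrow(coords), , drop = FALSE]
    if (nrow(coords) < 3L) stop("polygon needs at least 3 distinct vertices")
  }
  if (type == "line" && nrow(coords) < 2L) stop("line needs >= 2 vertices")
  structure(list(type = type, coords = coords), class = "geometry")
}

#' Axis-aligned rectangle polygon
#' @param xmin,ymin,xmax,ymax bounds.
#' @return polygon [geometry()].
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  geometry("polygon", rbind(c(xmin, ymin), c(xmax, ymin),
                            c(xmax, ymax), c(xmin, ymax)))
}

#' Construct a feature (geometry plus attributes)
#' @param geom a [geometry()].
#' @param ... named flat attributes.
#' @return object of class `feature`.
#' @export
feature <- function(geom, ...) {
  structure(list(geometry = geom, attributes = list(...)), class = "feature")
}

#' Construct a vector layer
#' @param features list of [feature()] objects.
#' @param crs coordinate reference label.
#' @return object of class `vector_layer`.
#' @export
vector_layer <- function(features = list(), crs = "LOCAL:metre") {
  structure(list(features = features, crs = crs), class = "vector_layer")
}

#' @export
print.vector_layer <- function(x, ...) {
  types <- vapply(x$features, function(f) f$geometry$type, character(1))
  cat("vector_layer:", length(x$features), "feature(s)")
  if (length(types)) cat(" (", paste(names(table(types)), table(types),
                                     collapse = ", "), ")")
  cat(", crs", x$crs, "\n")
  invisible(x)
}

#' Polygon area (shoelace formula)
#' @param poly polygon [geometry()].
#' @param unit `"m2"`, `"km2"` or `"ha"`.
#' @return area in the requested unit.
#' @export
polygon_area <- function(poly, unit = c("m2", "km2", "ha")) {
  unit <- match.arg(unit)
  p <- poly$coords
  n <- nrow(p)
  j <- c(2:n, 1L)
  a <- abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
  switch(unit, m2 = a, km2 = a / 1e6, ha = a / 1e4)
}

#' Polygon centroid
#' @param poly polygon [geometry()].
#' @return numeric (x, y).
#' @export
polygon_centroid <- function(poly) {
  p <- poly$coords
  n <- nrow(p)
  j <- c(2:n, 1L)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

#' Even-odd point-in-polygon test
#'
#' Ray casting with the half-open edge rule; points exactly on a vertex or
#' edge count as inside.
#'
#' @param x,y point coordinates (vectorised).
#' @param poly polygon [geometry()].
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  p <- poly$coords
  n <- nrow(p)
  px <- p[, 1]; py <- p[, 2]
  jx <- px[c(2:n, 1L)]; jy <- py[c(2:n, 1L)]
  vapply(seq_along(x), function(k) {
    xx <- x[k]; yy <- y[k]
    inside <- FALSE
    for (i in seq_len(n)) {
      x1 <- px[i]; y1 <- py[i]; x2 <- jx[i]; y2 <- jy[i]
      # on-edge check
      if (.on_segment(xx, yy, x1, y1, x2, y2)) return(TRUE)
      if ((y1 > yy) != (y2 > yy)) {
        xint <- x1 + (yy - y1) * (x2 - x1) / (y2 - y1)
        if (xx < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

.on_segment <- function(px, py, x1, y1, x2, y2, eps = 1e-9) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  if (abs(cross) > eps * (abs(x2 - x1) + abs(y2 - y1) + 1)) return(FALSE)
  dot <- (px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)
  len2 <- (x2 - x1)^2 + (y2 - y1)^2
  dot >= -eps && dot <= len2 + eps
}

# -- distances ----------------------------------------------------------------

.dist_point_seg <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) 0 else max(0, min(1, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

.segs_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o <- function(px, py, qx, qy, rx, ry) {
    v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
    sign(v)
  }
  o1 <- o(ax, ay, bx, by, cx, cy); o2 <- o(ax, ay, bx, by, dx, dy)
  o3 <- o(cx, cy, dx, dy, ax, ay); o4 <- o(cx, cy, dx, dy, bx, by)
  if (o1 != o2 && o3 != o4) return(TRUE)
  # collinear touching
  (o1 == 0 && .on_segment(cx, cy, ax, ay, bx, by)) ||
    (o2 == 0 && .on_segment(dx, dy, ax, ay, bx, by)) ||
    (o3 == 0 && .on_segment(ax, ay, cx, cy, dx, dy)) ||
    (o4 == 0 && .on_segment(bx, by, cx, cy, dx, dy))
}

.dist_seg_seg <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  if (.segs_intersect(ax, ay, bx, by, cx, cy, dx, dy)) return(0)
  min(.dist_point_seg(ax, ay, cx, cy, dx, dy),
      .dist_point_seg(bx, by, cx, cy, dx, dy),
      .dist_point_seg(cx, cy, ax, ay, bx, by),
      .dist_point_seg(dx, dy, ax, ay, bx, by))
}

.geom_segments <- function(g) {
  p <- g$coords
  if (g$type == "point") return(NULL)
  if (g$type == "polygon") p <- rbind(p, p[1, ])
  cbind(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE])
}

#' Minimum distance between two geometries
#'
#' Zero when the geometries intersect or one contains the other.
#'
#' @param g1,g2 [geometry()] objects.
#' @return distance in coordinate units (metres).
#' @export
geom_distance <- function(g1, g2) {
  # containment in polygons => 0
  for (pair in list(list(g1, g2), list(g2, g1))) {
    a <- pair[[1]]; b <- pair[[2]]
    if (a$type == "polygon" &&
        any(point_in_polygon(b$coords[, 1], b$coords[, 2], a)))
      return(0)
  }
  s1 <- .geom_segments(g1); s2 <- .geom_segments(g2)
  if (is.null(s1) && is.null(s2)) {
    return(min(sqrt(outer(g1$coords[, 1], g2$coords[, 1], "-")^2 +
                      outer(g1$coords[, 2], g2$coords[, 2], "-")^2)))
  }
  if (is.null(s1)) {
    d <- apply(g1$coords, 1, function(pt)
      min(apply(s2, 1, function(s)
        .dist_point_seg(pt[1], pt[2], s[1], s[2], s[3], s[4]))))
    return(min(d))
  }
  if (is.null(s2)) return(geom_distance(g2, g1))
  best <- Inf
  for (i in seq_len(nrow(s1)))
    for (j in seq_len(nrow(s2))) {
      d <- .dist_seg_seg(s1[i, 1], s1[i, 2], s1[i, 3], s1[i, 4],
                         s2[j, 1], s2[j, 2], s2[j, 3], s2[j, 4])
      if (d < best) best <- d
      if (best == 0) return(0)
    }
  best
}

#' Select features within a distance of a geometry
#'
#' Returns the features of `layer` lying within `distance_m` of
#' `zone` (equivalently, intersecting its buffer). `distance_m = 0` is a
#' plain intersection/containment test.
#'
#' @param layer a [vector_layer()].
#' @param zone a [geometry()] or a single [feature()].
#' @param distance_m buffer distance in metres (>= 0).
#' @return a [vector_layer()] with the selected features.
#' @export
features_within <- function(layer, zone, distance_m = 0) {
  if (inherits(zone, "feature")) zone <- zone$geometry
  if (!inherits(zone, "geometry")) stop("'zone' must be a geometry or feature")
  if (distance_m < 0) stop("distance must be non-negative")
  keep <- vapply(layer$features, function(f)
    geom_distance(f$geometry, zone) <= distance_m, logical(1))
  vector_layer(layer$features[keep], layer$crs)
}

#' Compass bearing from one point to another
#'
#' @param from,to numeric (x, y) coordinates.
#' @return bearing in degrees, 0 = north, clockwise, in \[0, 360).
#' @export
bearing_deg <- function(from, to) {
  (atan2(to[1] - from[1], to[2] - from[2]) * 180 / pi) %% 360
}
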