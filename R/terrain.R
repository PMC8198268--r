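#' Terrain slope and aspect (Horn's method)
#'
#' Finite-difference derivatives over each cell's 3 x 3 neighbourhood with
#' Horn's weights. Edge rows/columns are handled by replicating the border
#' cells; cells with any `NA` neighbour propagate `NA`.
#'
#' `compute_slope` returns the slope in degrees; `compute_aspect` the
#' downslope compass direction in degrees (0 = north, 90 = east), with flat
#' cells (zero gradient) set to `NA`.
#'
#' @param dem a [raster_grid()] of elevations in metres on a projected
#'   (metre-unit) coordinate system.
#' @return a [raster_grid()] of slope degrees / compass aspect degrees.
#' @export
compute_slope <- function(dem) {
  g <- .horn_gradient(dem)
  slope <- atan(sqrt(g$dzdx^2 + g$dzdy^2)) * 180 / pi
  raster_grid(slope, dem$xmin, dem$ymin, dem$cellsize, dem$crs)
}

#' @rdname compute_slope
#' @export
compute_aspect <- function(dem) {
  g <- .horn_gradient(dem)
  # downslope vector is -grad; compass angle measured clockwise from north
  asp <- (atan2(-g$dzdx, -g$dzdy) * 180 / pi) %% 360
  asp[g$dzdx == 0 & g$dzdy == 0] <- NA_real_
  raster_grid(asp, dem$xmin, dem$ymin, dem$cellsize, dem$crs)
}

# Horn 1981 weights: dz/dx = ((c+2f+i)-(a+2d+g))/(8*cell) on the 3x3 window
#   a b c
#   d e f      columns west -> east, rows north -> south
#   g h i
.horn_gradient <- function(dem) {
  if (!inherits(dem, "raster_grid")) stop("'dem' must be a raster_grid")
  if (.rg_geographic(dem))
    stop("DEM is in a geographic (degree) coordinate system; ",
         "reproject to a metre-unit projection first")
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2L || nc < 2L) stop("DEM too small for slope computation")
  # pad by edge replication
  zp <- z[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  i <- 2:(nr + 1L); j <- 2:(nc + 1L)
  nw <- zp[i - 1L, j - 1L]; n_ <- zp[i - 1L, j]; ne <- zp[i - 1L, j + 1L]
  w_ <- zp[i, j - 1L];                            e_ <- zp[i, j + 1L]
  sw <- zp[i + 1L, j - 1L]; s_ <- zp[i + 1L, j]; se <- zp[i + 1L, j + 1L]
  d <- 8 * dem$cellsize
  dzdx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / d
  # y axis points north = decreasing row index
  dzdy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / d
  list(dzdx = dzdx, dzdy = dzdy)
}
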