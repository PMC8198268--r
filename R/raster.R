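#' Raster grid container
#'
#' A minimal single-band raster: a numeric matrix with row 1 at the north
#' edge, an affine georeference given by the lower-left corner and square
#' cell size (metres of a projected coordinate system), and `NA` as the
#' internal nodata value.
#'
#' @param values numeric matrix (row 1 = northernmost row).
#' @param xmin,ymin coordinates of the lower-left corner, metres.
#' @param cellsize cell edge length, metres (> 0).
#' @param crs coordinate reference label; anything matching
#'   degree/geographic identifiers is rejected by the terrain functions.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cellsize = 25,
                        crs = "LOCAL:metre") {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (cellsize <= 0) stop("cellsize must be positive")
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize, crs = crs),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat("raster_grid: ", nrow(v), " rows x ", ncol(v), " cols, cell ",
      x$cellsize, " m, origin (", x$xmin, ", ", x$ymin, "), crs ",
      x$crs, "\n", sep = "")
  cat("  values: [", signif(min(v, na.rm = TRUE), 6), ", ",
      signif(max(v, na.rm = TRUE), 6), "], NA cells: ", sum(is.na(v)),
      "\n", sep = "")
  invisible(x)
}

.rg_xmax <- function(r) r$xmin + ncol(r$values) * r$cellsize
.rg_ymax <- function(r) r$ymin + nrow(r$values) * r$cellsize

#' Cell-center coordinates of a raster grid
#'
#' @param r a [raster_grid()].
#' @return list with vectors `x` (by column, west to east) and `y` (by row,
#'   north to south, matching matrix row order).
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xmin + (seq_len(nc) - 0.5) * r$cellsize,
       y = .rg_ymax(r) - (seq_len(nr) - 0.5) * r$cellsize)
}

.rg_geographic <- function(r)
  grepl("4326|longlat|geographic|degree|wgs84", tolower(r$crs))

.rg_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize),
                     c(b$xmin, b$ymin, b$cellsize))) &&
    identical(a$crs, b$crs)
}

# -- plain-text grid I/O (Esri ASCII grid) ------------------------------------

#' Read / write a raster as an Esri ASCII grid
#'
#' The `.asc` format stores the header (ncols, nrows, lower-left corner,
#' cellsize, nodata sentinel) followed by rows of values from the north edge
#' southwards, matching the internal matrix layout.
#'
#' @param r a [raster_grid()].
#' @param path file path.
#' @param nodata sentinel written in place of `NA` cells.
#' @param crs crs label to attach on read (the format itself carries none).
#' @return `read_ascii_grid` returns a [raster_grid()].
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)),
               paste("nrows", nrow(v)),
               paste("xllcorner", format(r$xmin, scientific = FALSE)),
               paste("yllcorner", format(r$ymin, scientific = FALSE)),
               paste("cellsize", format(r$cellsize, scientific = FALSE)),
               paste("NODATA_value", nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, crs = "LOCAL:metre") {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) >= 2L)
      hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need])))
    stop("not an ASCII grid (missing header fields): ", path)
  v <- matrix(scan(path, skip = 6, quiet = TRUE),
              nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA
  raster_grid(v, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
              cellsize = hdr$cellsize, crs = crs)
}

# -- reclassification ---------------------------------------------------------

#' Reclassify a raster to integer grades
#'
#' Either by a binned rubric (continuous input; left-closed bins) or by a
#' category map (categorical input). `NA` cells are preserved.
#'
#' @param r a [raster_grid()].
#' @param bins a [rubric_bins()] object (continuous reclassification).
#' @param map named numeric vector mapping category codes (names) to grades.
#' @param default grade for unmapped categories; if `NULL`, unmapped
#'   categories are an error.
#' @return a [raster_grid()] of grades.
#' @export
reclassify <- function(r, bins = NULL, map = NULL, default = NULL) {
  v <- r$values
  if (!is.null(bins)) {
    out <- matrix(NA_real_, nrow(v), ncol(v))
    ok <- !is.na(v)
    out[ok] <- bin_grade(v[ok], bins)
  } else if (!is.null(map)) {
    out <- matrix(NA_real_, nrow(v), ncol(v))
    ok <- !is.na(v)
    idx <- match(as.character(v[ok]), names(map))
    g <- unname(map[idx])
    if (anyNA(g)) {
      if (is.null(default))
        stop("unmapped category value(s): ",
             paste(sort(unique(v[ok][is.na(idx)])), collapse = ", "))
      g[is.na(g)] <- default
    }
    out[ok] <- g
  } else stop("supply either 'bins' or 'map'")
  raster_grid(out, r$xmin, r$ymin, r$cellsize, r$crs)
}
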