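# Independent oracles used across the suite. Each deliberately reimplements
# the operation it checks by the most transparent method available
# (exhaustive enumeration, scalar loops, analytic geometry) and shares no
# code with the package internals.

# exact Jenks by enumerating every ordered partition of the sorted sample
brute_jenks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssq <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(numeric(0))
  # choose k-1 cut positions among the n-1 gaps
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf; bestcut <- NULL
  for (ci in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, ci], n)
    tot <- 0
    for (j in seq_len(k)) tot <- tot + ssq(x[(b[j] + 1):b[j + 1]])
    if (tot < best - 1e-12) { best <- tot; bestcut <- cuts[, ci] }
  }
  x[bestcut]   # class maxima
}

brute_jenks_class <- function(v, breaks) 1L + sum(breaks < v)

# scalar-loop Horn gradient (edge replication), independent of the
# vectorised implementation
brute_horn <- function(z, cell) {
  nr <- nrow(z); nc <- ncol(z)
  at <- function(i, j) z[min(max(i, 1), nr), min(max(j, 1), nc)]
  slope <- matrix(NA_real_, nr, nc)
  aspect <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    a <- at(i - 1, j - 1); b <- at(i - 1, j); c_ <- at(i - 1, j + 1)
    d <- at(i, j - 1);                         f <- at(i, j + 1)
    g <- at(i + 1, j - 1); h <- at(i + 1, j); ii <- at(i + 1, j + 1)
    dzdx <- ((c_ + 2 * f + ii) - (a + 2 * d + g)) / (8 * cell)
    dzdy <- ((a + 2 * b + c_) - (g + 2 * h + ii)) / (8 * cell)
    slope[i, j] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
    if (dzdx == 0 && dzdy == 0) aspect[i, j] <- NA
    else aspect[i, j] <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  }
  list(slope = slope, aspect = aspect)
}

# winding-number point-in-polygon (different algorithm from the package's
# even-odd ray casting)
winding_inside <- function(x, y, coords) {
  n <- nrow(coords)
  ang <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(coords[i, 2] - y, coords[i, 1] - x)
    a2 <- atan2(coords[j, 2] - y, coords[j, 1] - x)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    ang <- ang + d
  }
  abs(ang) > pi
}

# brute-force zonal values: loop every cell, test its center
brute_zonal_values <- function(r, poly) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  ymax <- r$ymin + nr * r$cellsize
  out <- c()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cx <- r$xmin + (j - 0.5) * r$cellsize
    cy <- ymax - (i - 0.5) * r$cellsize
    if (winding_inside(cx, cy, poly$coords) && !is.na(r$values[i, j]))
      out <- c(out, r$values[i, j])
  }
  out
}

# an irregular (non-convex) test polygon; coefficients chosen so no edge
# aligns with the rational cell-center lattices used in the tests (on-edge
# points are a documented tie-break, not part of the oracle comparison)
irregular_polygon <- function(cx, cy, scale) {
  geometry("polygon", cbind(
    cx + scale * c(-1.013, -0.207, 0.311, 0.983, 0.709, 0.117, -0.571, -1.097),
    cy + scale * c(-0.811, -0.989, -0.413, -0.607, 0.591, 1.009, 0.787, 0.103)))
}

# reference lake table row by name
lake_row <- function(name) {
  lakes <- romanian_lakes()
  lakes[lakes$name == name, , drop = FALSE]
}

# a reference-row scene specification reused across test files
merhei_spec <- function(seed = 1L) {
  row <- lake_row("Merhei")
  scene_spec(grades = as.list(row[c("W", "R", "A", "a", "S", "T", "I", "C")]),
             hazards = list(slope = row$slope, aspect = row$aspect,
                            permeability = row$permeability),
             seed = seed, protected = TRUE, name = "Merhei")
}
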