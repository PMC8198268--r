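test_that("zonal statistics on a constant raster are the constant", {
  r <- raster_grid(matrix(7, 20, 20), cellsize = 10)
  zone <- rect_polygon(20, 20, 150, 150)
  expect_equal(zonal_stats(r, zone, "max"), 7)
  expect_equal(zonal_stats(r, zone, "mean"), 7)
  expect_equal(zonal_stats(r, zone, "mode"), 7)
})

test_that("class percentages report constructed splits and sum to 100", {
  v <- matrix(2, 10, 10)
  v[1:3, ] <- 1                      # 30 / 70 split
  r <- raster_grid(v, cellsize = 10)
  zone <- rect_polygon(0, 0, 100, 100)
  pct <- zonal_stats(r, zone, "class_percentages")
  expect_equal(unname(pct[c("1", "2")]), c(30, 70))
  expect_equal(sum(pct), 100, tolerance = 1e-9)

  set.seed(23)
  rr <- raster_grid(matrix(sample(1:5, 400, TRUE), 20, 20), cellsize = 5)
  poly <- irregular_polygon(50, 50, 38)
  expect_equal(sum(zonal_stats(rr, poly, "class_percentages")), 100,
               tolerance = 1e-9)
})

test_that("zonal statistics equal the brute-force cell loop", {
  set.seed(19)
  v <- matrix(stats::runif(64 * 64, 0, 50), 64, 64)
  v[sample(length(v), 100)] <- NA
  r <- raster_grid(v, cellsize = 4)
  poly <- irregular_polygon(128, 128, 90)
  want <- brute_zonal_values(r, poly)
  expect_equal(sort(zonal_values(r, poly)), sort(want))
  expect_equal(zonal_stats(r, poly, "max"), max(want))
  expect_equal(zonal_stats(r, poly, "mean"), mean(want))
  expect_equal(zonal_stats(r, poly, "percentiles"),
               stats::quantile(want, c(0.25, 0.5, 0.75), type = 7))
})

test_that("empty zones raise a distinguishable error", {
  r <- raster_grid(matrix(0, 10, 10), cellsize = 10)
  off <- rect_polygon(5000, 5000, 5100, 5100)
  expect_error(zonal_stats(r, off, "max"), "no valid raster cells")
  all_na <- raster_grid(matrix(NA_real_, 10, 10), cellsize = 10)
  expect_error(zonal_stats(all_na, rect_polygon(0, 0, 100, 100), "mean"),
               "no valid raster cells")
})

test_that("class fractions count the requested codes", {
  v <- matrix(3, 10, 10); v[, 6:10] <- 5
  r <- raster_grid(v, cellsize = 10)
  zone <- rect_polygon(0, 0, 100, 100)
  expect_equal(class_fraction(r, zone, 3), 50)
  expect_equal(class_fraction(r, zone, c(3, 5)), 100)
  expect_equal(class_fraction(r, zone, 9), 0)

  set.seed(29)
  mosaic <- raster_grid(matrix(sample(1:4, 900, TRUE), 30, 30), cellsize = 5)
  poly <- irregular_polygon(75, 75, 55)
  want <- brute_zonal_values(mosaic, poly)
  expect_equal(class_fraction(mosaic, poly, c(2, 4)),
               100 * sum(want %in% c(2, 4)) / length(want))
})

test_that("mode ties break toward the lowest grade", {
  expect_equal(stat_mode(c(1, 1, 5, 5)), 1)
  expect_equal(stat_mode(c(4, 4, 3, 3, 5)), 3)
  expect_error(stat_mode(NA), "no values")
})

test_that("nearest-point allocation equals exhaustive search", {
  tmpl <- raster_grid(matrix(0, 16, 16), cellsize = 10)
  one <- vector_layer(list(
    feature(geometry("point", matrix(c(80, 80), 1)), v = 42)))
  expect_true(all(nearest_point_surface(one, "v", tmpl)$values == 42))

  # equidistant cell goes to the earlier feature
  two <- vector_layer(list(
    feature(geometry("point", matrix(c(40, 80), 1)), v = 1),
    feature(geometry("point", matrix(c(110, 80), 1)), v = 2)))
  mid <- nearest_point_surface(two, "v", tmpl)
  expect_equal(mid$values[1, 8], 1)  # col-8 centers (x = 75) are equidistant

  set.seed(37)
  pts <- lapply(1:10, function(i)
    feature(geometry("point", matrix(stats::runif(2, 0, 160), 1)), v = i))
  layer <- vector_layer(pts)
  surf <- nearest_point_surface(layer, "v", tmpl)
  xy <- t(vapply(pts, function(f) f$geometry$coords[1, ], numeric(2)))
  for (i in seq(1, 16, by = 3)) for (j in seq(1, 16, by = 3)) {
    cx <- (j - 0.5) * 10; cy <- 160 - (i - 0.5) * 10
    d2 <- (xy[, 1] - cx)^2 + (xy[, 2] - cy)^2
    expect_equal(surf$values[i, j], which.min(d2))
  }
  expect_error(nearest_point_surface(vector_layer(list()), "v", tmpl),
               "empty")
})

test_that("inverse-distance weighting interpolates between points", {
  tmpl <- raster_grid(matrix(0, 8, 8), cellsize = 10)
  two <- vector_layer(list(
    feature(geometry("point", matrix(c(5, 75), 1)), v = 0),
    feature(geometry("point", matrix(c(75, 75), 1)), v = 10)))
  s <- nearest_point_surface(two, "v", tmpl, power = 2)
  expect_equal(s$values[1, 1], 0)    # at the first point
  expect_equal(s$values[1, 8], 10)   # at the second
  expect_true(all(diff(s$values[1, ]) > 0))  # monotone between them
})

test_that("the cell-wise index surface matches the tabular engine", {
  row <- lake_row("Snagov")
  n <- 6
  const <- function(v) raster_grid(matrix(v, n, n), cellsize = 10)
  grades <- lapply(as.list(row[c("W", "R", "A", "a", "S", "T", "I", "C")]),
                   const)
  hazards <- list(slope = const(row$slope), aspect = const(row$aspect),
                  permeability = const(row$permeability))
  surf <- per_pixel_index(grades, wrastic_weights(), hazards)
  want <- compute_wrastic(as.list(row))
  expect_true(all(surf$wrastic$values == want))
  expect_true(all(surf$hi$values == row$slope + row$aspect + row$permeability))
  expect_true(all(surf$wrastic_hi$values ==
                    want * (row$slope + row$aspect + row$permeability)))
  expect_true(all(surf$state$values == 2))  # Snagov is semi-degraded

  # nodata propagates cell-wise
  g2 <- grades; g2$W$values[2, 2] <- NA
  surf2 <- per_pixel_index(g2, wrastic_weights(), hazards)
  expect_true(is.na(surf2$wrastic$values[2, 2]))
  expect_true(is.na(surf2$state$values[2, 2]))
  expect_false(anyNA(surf2$wrastic$values[-2, ]))

  # random aligned stacks equal the scalar loop
  set.seed(41)
  rnd <- lapply(stats::setNames(1:8, c("W", "R", "A", "a", "S", "T", "I", "C")),
                function(k) const(0) )
  for (nm in c("W", "R", "A", "a", "S", "T", "I", "C"))
    rnd[[nm]]$values[] <- sample(1:4, n * n, TRUE)
  hz <- list(slope = const(0), aspect = const(0), permeability = const(0))
  hz$slope$values[] <- sample(c(1, 3, 4, 5), n * n, TRUE)
  hz$aspect$values[] <- sample(c(1, 3, 5), n * n, TRUE)
  hz$permeability$values[] <- sample(c(1, 3, 5), n * n, TRUE)
  surf3 <- per_pixel_index(rnd, wrastic_weights(), hz)
  w <- wrastic_weights()
  for (i in 1:n) for (j in 1:n) {
    want_ij <- sum(vapply(names(rnd), function(nm)
      w[[nm]] * rnd[[nm]]$values[i, j], numeric(1)))
    expect_equal(surf3$wrastic$values[i, j], want_ij)
  }

  # misaligned grids are refused
  bad <- grades
  bad$W <- raster_grid(matrix(1, n, n), xmin = 5, cellsize = 10)
  expect_error(per_pixel_index(bad, wrastic_weights(), hazards),
               "aligned")
})
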