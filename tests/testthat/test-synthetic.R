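test_that("identical specifications produce identical scenes", {
  s1 <- make_scene(merhei_spec(7))
  s2 <- make_scene(merhei_spec(7))
  expect_identical(s1$dem$values, s2$dem$values)
  expect_identical(s1$landcover$values, s2$landcover$values)
  expect_identical(s1$vegetation$values, s2$vegetation$values)
  expect_identical(s1$irrigation$values, s2$irrigation$values)
  expect_identical(s1$lake$geometry$coords, s2$lake$geometry$coords)
  s3 <- make_scene(merhei_spec(8))
  expect_false(identical(s1$landcover$values, s3$landcover$values))
})

test_that("scene generation does not disturb the caller's RNG stream", {
  set.seed(99); before <- stats::runif(3)
  set.seed(99); invisible(make_scene(merhei_spec(7))); after <- stats::runif(3)
  expect_identical(before, after)
})

test_that("infeasible grade requests are rejected with an explanation", {
  row <- lake_row("Merhei")
  g <- as.list(row[c("W", "R", "A", "a", "S", "T", "I", "C")])
  expect_error(scene_spec(g, list(slope = 2, aspect = 3, permeability = 1)),
               "slope grade 2")
  g2 <- g; g2$T <- 2L
  expect_error(scene_spec(g2, list(slope = 1, aspect = 3, permeability = 1)),
               "not reachable")
  g3 <- g; g3$I <- 4L
  expect_error(scene_spec(g3, list(slope = 1, aspect = 3, permeability = 1)),
               "not reachable")
  expect_error(scene_spec(g, list(slope = 1, aspect = 3, permeability = 1),
                          cells_x = 99), "divisible by 4")
})

test_that("land-cover fractions are recovered by brute-force cell counts", {
  spec <- merhei_spec(3)
  lcv <- make_landcover(spec)
  ws <- rect_polygon(2 * lcv$landcover$cellsize, 2 * lcv$landcover$cellsize,
                     102 * lcv$landcover$cellsize, 82 * lcv$landcover$cellsize)
  veg <- brute_zonal_values(lcv$vegetation, ws)
  expect_equal(100 * sum(veg == 1) / length(veg), spec$cover_pct,
               tolerance = 0.5)
  irr <- brute_zonal_values(lcv$irrigation, ws)
  expect_equal(100 * sum(irr == 1) / length(irr), spec$irrig_pct,
               tolerance = 0.5)
  ag <- brute_zonal_values(lcv$landcover, ws)
  expect_equal(100 * sum(ag == lcv$legend$agricultural) / length(ag),
               spec$agri_pct, tolerance = 0.5)
})

test_that("extreme cover fractions map to the extreme grades", {
  row <- lake_row("Merhei")
  g <- as.list(row[c("W", "R", "A", "a", "S", "T", "I", "C")])
  g$C <- 1L   # >50% natural vegetation
  sp <- scene_spec(g, list(slope = 1, aspect = 3, permeability = 1), seed = 2)
  sc <- make_scene(sp)
  expect_identical(evaluate_lake_geospatial(sc)$grades$C, 1L)
  g$C <- 5L   # <5% vegetation
  sp <- scene_spec(g, list(slope = 1, aspect = 3, permeability = 1), seed = 2)
  sc <- make_scene(sp)
  expect_identical(evaluate_lake_geospatial(sc)$grades$C, 5L)
})

test_that("the DEM realises the requested slope and aspect grades", {
  row <- lake_row("Merhei")
  g <- as.list(row[c("W", "R", "A", "a", "S", "T", "I", "C")])
  for (sl in c(1L, 3L, 4L, 5L)) for (asp in c(1L, 3L, 5L)) {
    sp <- scene_spec(g, list(slope = sl, aspect = asp, permeability = 3),
                     seed = 4)
    res <- evaluate_lake_geospatial(make_scene(sp))
    expect_identical(res$hazards$slope, sl, info = paste(sl, asp))
    expect_identical(res$hazards$aspect, asp, info = paste(sl, asp))
    expect_identical(res$hazards$permeability, 3L)
  }
})

test_that("feature placement realises the categorical indicator grades", {
  row <- lake_row("Merhei")
  g <- as.list(row[c("W", "R", "A", "a", "S", "T", "I", "C")])
  h <- list(slope = 1, aspect = 3, permeability = 1)

  g$R <- 5L  # infrastructure within 50 m plus motorized sports
  sc <- make_scene(scene_spec(g, h, seed = 5))
  expect_identical(evaluate_lake_geospatial(sc)$grades$R, 5L)

  g$R <- 2L; g$T <- 0L
  sc <- make_scene(scene_spec(g, h, seed = 5))
  res <- evaluate_lake_geospatial(sc)
  expect_identical(res$grades$R, 2L)
  expect_identical(res$grades$T, 0L)

  g$T <- 5L; g$I <- 5L; g$W <- 3L
  sc <- make_scene(scene_spec(g, h, seed = 5))
  res <- evaluate_lake_geospatial(sc)
  expect_identical(res$grades$T, 5L)
  expect_identical(res$grades$I, 5L)
  expect_identical(res$grades$W, 3L)
})

test_that("scenes survive a write/read round trip unchanged", {
  sc <- make_scene(merhei_spec(6))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  expect_true(all(file.exists(file.path(dir, c("dem.asc", "landcover.asc",
                                               "vegetation.asc",
                                               "irrigation.asc",
                                               "vectors.geojson",
                                               "manifest.json")))))
  sc2 <- read_scene(dir)
  r1 <- evaluate_lake_geospatial(sc)
  r2 <- evaluate_lake_geospatial(sc2)
  expect_identical(unlist(r1$grades), unlist(r2$grades))
  expect_identical(unlist(r1$hazards), unlist(r2$hazards))
  expect_identical(r1$state, r2$state)
  expect_identical(sc2$truth$state, sc$truth$state)
})

test_that("rows with the rubric-incompatible slope grade are substituted", {
  row <- lake_row("Siutghiol")
  expect_warning(sc <- make_scene_for_lake_row(row, seed = 9),
                 "nearest feasible")
  expect_identical(sc$truth$hazards$slope, 3L)
  res <- evaluate_lake_geospatial(sc)
  expect_identical(res$state, row$state)
})
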