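#' @title Geospatial evaluation of a lake watershed
#' @name geospatial
#' @description Derives every indicator and hazard grade from raster and
#'   vector layers and runs the per-lake workflow: terrain derivatives,
#'   land-cover fractions, feature predicates, rubric scoring, watershed
#'   aggregation, the cell-wise index surface and its class percentages.
NULL

.scene_layers <- c("dem", "landcover", "vegetation", "irrigation",
                   "legend", "lake", "watershed", "roads", "railways",
                   "plants", "settlements", "industry", "infrastructure",
                   "protected", "soil")

#' Rasterize soil-texture polygons to a permeability grade raster
#'
#' Cells take the grade of the last polygon (in layer order) whose interior
#' contains their center; uncovered cells are `NA`.
#'
#' @param soil a [vector_layer()] of polygons with a `texture` attribute
#'   (`"clay"`, `"sand"` or `"gravel"`).
#' @param template a [raster_grid()] giving the output geometry.
#' @return a [raster_grid()] of permeability grades.
#' @export
permeability_raster <- function(soil, template) {
  out <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  for (f in soil$features) {
    g <- score_permeability(f$attributes$texture)
    m <- cells_in_polygon(template, f$geometry)
    out[m] <- g
  }
  raster_grid(out, template$xmin, template$ymin, template$cellsize,
              template$crs)
}

.aggregate_hazard <- function(grades, how = "mode") {
  grades <- grades[!is.na(grades)]
  as.integer(switch(how,
                    mode = stat_mode(grades),
                    max  = max(grades),
                    mean = round_half_up(mean(grades)),
                    stop("unknown hazard aggregation: ", how)))
}

#' Evaluate a lake from its raster/vector layers
#'
#' Runs the full per-lake workflow on a scene: derives the seven indicator
#' grades and three hazard grades from the layers, aggregates them into the
#' index, classifies the degradation state and records the percentages of
#' the per-cell state surface within the watershed.
#'
#' @param scene named list of layers: `dem`, `landcover`, `vegetation`
#'   (0/1 natural-vegetation mask), `irrigation` (0/1 mask)
#'   ([raster_grid()]s), `legend` (named list of land-cover codes with at
#'   least `agricultural`), `lake` (feature with
#'   `sports` and `access` attributes), `watershed` (polygon feature or
#'   geometry), `roads`/`railways` (line layers with `category`), `plants`
#'   (points with `stage`), `settlements` (points with `population`),
#'   `industry` (features with `kind`), `infrastructure` (points),
#'   `protected` (polygon layer), `soil` (polygons with `texture`).
#' @param weights a [wrastic_weights()] scheme.
#' @param type_rule a [hi_type_rule()].
#' @param thresholds see [class_thresholds()].
#' @param config rubric configuration, see [rubric_config()].
#' @return a `degradation_result` (see [evaluate_lake()]) with additional
#'   fields: `grades` (the derived indicator grades), `hazards` (the
#'   derived hazard grades), `class_percentages` (state shares of the
#'   watershed surface), `area_km2` and `protected`.
#' @export
evaluate_lake_geospatial <- function(scene, weights = wrastic_weights(),
                                     type_rule = hi_type_rule(),
                                     thresholds = class_thresholds(),
                                     config = rubric_config()) {
  miss <- setdiff(.scene_layers, names(scene))
  if (length(miss))
    stop("missing scene layer(s): ", paste(miss, collapse = ", "))

  lake_f <- scene$lake
  lake <- if (inherits(lake_f, "feature")) lake_f$geometry else lake_f
  ws_f <- scene$watershed
  ws <- if (inherits(ws_f, "feature")) ws_f$geometry else ws_f
  legend <- scene$legend
  agg <- config$hazard_aggregation %||% "mode"

  # -- watershed size --------------------------------------------------------
  area_km2 <- polygon_area(ws, "km2")
  gS <- score_watershed_size(area_km2)

  # -- land-cover fractions --------------------------------------------------
  gA <- score_agricultural_land(
    class_fraction(scene$landcover, ws, legend$agricultural),
    scale = config$agricultural_scale %||% "extended_5bin")
  gC <- score_cover(class_fraction(scene$vegetation, ws, 1))
  ga <- score_irrigation(class_fraction(scene$irrigation, ws, 1))

  # -- features in the watershed --------------------------------------------
  plants <- features_within(scene$plants, ws, 0)
  stages <- vapply(plants$features, function(f) f$attributes$stage,
                   character(1))
  settl <- features_within(scene$settlements, ws, 0)
  gW <- score_wastewater(stages, length(settl$features) > 0L)

  infra <- features_within(scene$infrastructure, lake, 50)
  gR <- score_recreation(lake_f$attributes$sports %||% "none",
                         lake_f$attributes$access %||% "by_car",
                         length(infra$features) > 0L)

  transport <- c(
    vapply(features_within(scene$roads, ws, 0)$features,
           function(f) f$attributes$category, character(1)),
    vapply(features_within(scene$railways, ws, 0)$features,
           function(f) f$attributes$category, character(1)))
  gT <- score_transport(transport)

  ind <- features_within(scene$industry, ws, 0)
  kinds <- vapply(ind$features, function(f) f$attributes$kind, character(1))
  expl <- if ("mine_quarry_landfill" %in% kinds) "mine_quarry_landfill"
          else if ("exploitation_perimeter" %in% kinds) "exploitation_perimeter"
          else "none"
  gI <- score_industry("industrial" %in% kinds, expl)

  # -- hazard grades over the watershed -------------------------------------
  slope_r <- compute_slope(scene$dem)
  in_ws <- cells_in_polygon(slope_r, ws)
  slope_vals <- slope_r$values[in_ws]
  slope_vals <- slope_vals[!is.na(slope_vals)]
  if (length(slope_vals) == 0L)
    stop("watershed contains no valid DEM cells")
  slope_grades <- score_slope(slope_vals, slope_vals)
  h_slope <- .aggregate_hazard(slope_grades, agg)

  aspect_r <- compute_aspect(scene$dem)
  cc <- cell_centers(aspect_r)
  idx <- which(in_ws, arr.ind = TRUE)
  ctr <- polygon_centroid(lake)
  bearings <- (atan2(ctr[1] - cc$x[idx[, 2]], ctr[2] - cc$y[idx[, 1]]) *
                 180 / pi) %% 360
  asp_vals <- aspect_r$values[in_ws]
  cuts <- config$aspect_cutoffs %||% c(near = 45, far = 135)
  aspect_grades <- rep(3L, length(asp_vals))   # flat cells are neutral
  ok <- !is.na(asp_vals)
  aspect_grades[ok] <- score_aspect(asp_vals[ok], bearings[ok],
                                    near = cuts[[1]], far = cuts[[2]])
  h_aspect <- .aggregate_hazard(aspect_grades, agg)

  perm_r <- permeability_raster(scene$soil, scene$dem)
  h_perm <- .aggregate_hazard(perm_r$values[in_ws], agg)

  grades <- list(W = gW, R = gR, A = gA, a = ga, S = gS, T = gT, I = gI,
                 C = gC)
  hazards <- list(slope = h_slope, aspect = h_aspect, permeability = h_perm)
  res <- evaluate_lake(grades, hazards, weights, type_rule, thresholds)

  # -- cell-wise state surface and class percentages ------------------------
  tmpl <- scene$dem
  const_r <- function(v) {
    m <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values))
    m[in_ws] <- v
    raster_grid(m, tmpl$xmin, tmpl$ymin, tmpl$cellsize, tmpl$crs)
  }
  sg <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values))
  sg[in_ws] <- score_slope(slope_r$values[in_ws], slope_vals)
  ag <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values))
  ag[in_ws] <- aspect_grades
  pg <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values))
  pg[in_ws] <- perm_r$values[in_ws]
  mk <- function(m) raster_grid(m, tmpl$xmin, tmpl$ymin, tmpl$cellsize,
                                tmpl$crs)
  surf <- per_pixel_index(
    grade_rasters = lapply(grades, const_r),
    weights = weights,
    hazard_rasters = list(slope = mk(sg), aspect = mk(ag),
                          permeability = mk(pg)),
    type_rule = type_rule, thresholds = thresholds)
  pct <- zonal_stats(surf$state, ws, "class_percentages")
  lev <- c("natural", "semi_degraded", "degraded")
  cp <- setNames(numeric(3), lev)
  cp[as.integer(names(pct))] <- pct

  prot <- length(features_within(scene$protected,
                                 geometry("point", matrix(ctr, 1)), 0)$features) > 0L

  res$grades <- grades
  res$hazards <- hazards
  res$class_percentages <- cp
  res$area_km2 <- area_km2
  res$protected <- prot
  res$surface <- surf
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
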