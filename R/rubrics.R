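#' @title Scoring rubrics for the degradation indicators
#' @description Functions converting raw watershed measurements
#'   (percentages, areas, categories, treatment stages) into the integer
#'   grades used by the index. All binned rubrics are left-closed,
#'   right-open (\code{[a, b)}), with the final bin closed, so contiguous
#'   printed intervals form a partition of the measurement domain.
#' @name rubrics
NULL

# -- generic binned rubric ----------------------------------------------------

#' Construct a binned rubric
#'
#' @param edges strictly increasing interior thresholds, in the units of the
#'   measured quantity.
#' @param grades integer grades, one per bin (`length(edges) + 1`).
#' @return an object of class `rubric_bins`.
#' @export
rubric_bins <- function(edges, grades) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  if (length(grades) != length(edges) + 1L)
    stop("need length(edges) + 1 grades")
  if (any(grades != round(grades)) || any(grades < 0) || any(grades > 5))
    stop("grades must be integers in 0..5")
  structure(list(edges = as.numeric(edges), grades = as.integer(grades)),
            class = "rubric_bins")
}

#' Apply a binned rubric (left-closed convention)
#' @param x numeric values within the rubric domain.
#' @param bins a [rubric_bins()] object.
#' @return integer grades.
#' @export
bin_grade <- function(x, bins) {
  stopifnot(inherits(bins, "rubric_bins"))
  bins$grades[findInterval(x, bins$edges) + 1L]
}

# -- category tables (sub-indicator grades) -----------------------------------

.transport_grades <- c(
  highway_or_ring        = 5L,
  national_road          = 4L,
  main_railway           = 4L,
  county_or_local_road   = 3L,
  unpaved_road           = 1L,
  narrow_tourist_railway = 1L,
  none                   = 0L
)

.treatment_grades <- c(primary = 3L, secondary = 2L, tertiary = 1L)

.texture_grades <- c(clay = 5L, sand = 3L, gravel = 1L)

.sports_grades <- c(motorized = 5L, non_motorized = 4L, none = 0L)
.access_grades <- c(by_car = 3L, pedestrian = 2L, prohibited = 1L)

# -- indicator rubrics --------------------------------------------------------

#' Grade a wastewater treatment stage
#'
#' Primary treatment is the least effective and carries the worst grade.
#'
#' @param stage one of `"primary"`, `"secondary"`, `"tertiary"`.
#' @return integer grade 3/2/1.
#' @export
score_treatment_stage <- function(stage) {
  g <- .treatment_grades[match(stage, names(.treatment_grades))]
  if (anyNA(g)) stop("unknown treatment stage: ",
                     paste(setdiff(stage, names(.treatment_grades)),
                           collapse = ", "))
  unname(g)
}

#' Grade the wastewater indicator (W)
#'
#' 0 when the watershed holds neither settlements nor treatment plants;
#' otherwise the worst (maximum) stage grade among plants influencing the
#' watershed.
#'
#' @param stages character vector of treatment stages of plants in the
#'   watershed (may be empty).
#' @param settlements_present logical flag.
#' @return integer grade 0..3.
#' @export
score_wastewater <- function(stages, settlements_present) {
  if (length(stages) == 0L && !isTRUE(settlements_present)) return(0L)
  if (length(stages) == 0L) return(0L)
  max(score_treatment_stage(stages))
}

#' Grade the recreation indicator (R)
#'
#' Maximum of the applicable sub-grades: water sports (motorized 5,
#' non-motorized 4), access (by car 3, pedestrian 2, prohibited 1) and
#' tourist infrastructure within 50 m of the shore (present 4, absent 0).
#'
#' @param sports `"motorized"`, `"non_motorized"` or `"none"`.
#' @param access `"by_car"`, `"pedestrian"` or `"prohibited"`.
#' @param infrastructure_within_50m logical.
#' @return integer grade 1..5.
#' @export
score_recreation <- function(sports, access, infrastructure_within_50m) {
  if (!sports %in% names(.sports_grades)) stop("unknown sports category: ", sports)
  if (!access %in% names(.access_grades)) stop("unknown access category: ", access)
  max(.sports_grades[[sports]], .access_grades[[access]],
      if (isTRUE(infrastructure_within_50m)) 4L else 0L)
}

#' Grade permanently irrigated share of the watershed (a)
#' @param pct percent of the watershed under permanent irrigation, 0-100.
#' @return integer grade 1..5.
#' @export
score_irrigation <- function(pct) {
  if (any(pct < 0 | pct > 100)) stop("percentage out of range 0-100")
  bin_grade(pct, rubric_bins(c(10, 25, 50, 75), 1:5))
}

#' Grade agricultural land share of the watershed (A)
#'
#' The printed rubric has three bins (<20, 20-40, >40), but the reference
#' evaluations contain grades up to 5; the default extended five-bin scale
#' (<20, 20-40, 40-60, 60-80, >=80) is the only one consistent with them.
#'
#' @param pct percent of the watershed used for agriculture, 0-100.
#' @param scale `"extended_5bin"` (default) or `"printed_3bin"`.
#' @return integer grade.
#' @export
score_agricultural_land <- function(pct, scale = c("extended_5bin", "printed_3bin")) {
  scale <- match.arg(scale)
  if (any(pct < 0 | pct > 100)) stop("percentage out of range 0-100")
  if (scale == "printed_3bin")
    bin_grade(pct, rubric_bins(c(20, 40), 1:3))
  else
    bin_grade(pct, rubric_bins(c(20, 40, 60, 80), 1:5))
}

#' Grade the size of the watershed (S)
#' @param area_km2 watershed area in square kilometres (> 0).
#' @return integer grade 1..5.
#' @export
score_watershed_size <- function(area_km2) {
  if (any(area_km2 <= 0)) stop("watershed area must be positive")
  bin_grade(area_km2, rubric_bins(c(38.85, 155.39, 388.47, 1942.35), 1:5))
}

#' Grade the transport indicator (T)
#'
#' Maximum grade over the road/railway categories present in the watershed:
#' highways or ring roads 5, national roads 4, main railways 4, county or
#' local roads 3, unpaved roads 1, narrow-gauge tourist railways 1, none 0.
#'
#' @param categories character vector of categories present (may be empty).
#' @return integer grade 0..5.
#' @export
score_transport <- function(categories) {
  categories <- setdiff(categories, "none")
  if (length(categories) == 0L) return(0L)
  g <- .transport_grades[match(categories, names(.transport_grades))]
  if (anyNA(g)) stop("unknown transport category: ",
                     paste(categories[is.na(g)], collapse = ", "))
  max(g)
}

#' Grade the industry indicator (I)
#'
#' Maximum of the industrial sub-grade (present 3, absent 0) and the
#' exploitation sub-grade (mines/quarries/landfills 5, exploitation
#' perimeter 1, none 0).
#'
#' @param industrial_present logical.
#' @param exploitation `"mine_quarry_landfill"`, `"exploitation_perimeter"`
#'   or `"none"`.
#' @return integer grade 0..5.
#' @export
score_industry <- function(industrial_present,
                           exploitation = c("none", "mine_quarry_landfill",
                                            "exploitation_perimeter")) {
  exploitation <- match.arg(exploitation)
  e <- switch(exploitation, mine_quarry_landfill = 5L,
              exploitation_perimeter = 1L, none = 0L)
  max(if (isTRUE(industrial_present)) 3L else 0L, e)
}

#' Grade natural vegetation cover (C)
#'
#' Vegetation filters pollutants, so high cover earns the lowest grade.
#'
#' @param pct percent of the watershed under natural vegetation, 0-100.
#' @return integer grade 1..5 (5 = under 5 percent cover).
#' @export
score_cover <- function(pct) {
  if (any(pct < 0 | pct > 100)) stop("percentage out of range 0-100")
  bin_grade(pct, rubric_bins(c(5, 20, 35, 50), c(5L, 4L, 3L, 2L, 1L)))
}

# -- hazard rubrics -----------------------------------------------------------

#' Grade terrain slope by watershed quartile
#'
#' Grades a slope value by its quartile within the slope distribution of its
#' own watershed: below the 25th percentile 1, 25th-50th 3, 50th-75th 4,
#' above the 75th 5. The printed scale skips grade 2. Percentiles use linear
#' interpolation between order statistics; ties follow the left-closed
#' convention (a value equal to a percentile falls in the upper bin).
#'
#' @param slope_value slope in degrees (vectorised).
#' @param distribution non-empty numeric sample of watershed slopes.
#' @return integer grade in \{1, 3, 4, 5\}.
#' @export
score_slope <- function(slope_value, distribution) {
  if (length(distribution) == 0L) stop("empty slope distribution")
  q <- stats::quantile(distribution, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  g <- c(1L, 3L, 4L, 5L)
  g[findInterval(slope_value, q) + 1L]
}

#' Grade slope aspect by exposure toward the lake
#'
#' Operationalises "exposure privileges the accumulation of pollutants" as
#' angular proximity between the downslope aspect of a cell and the compass
#' bearing from the cell to the lake centroid: within `near` degrees the
#' slope drains toward the lake (grade 5), beyond `far` degrees it drains
#' away (grade 1), in between it is neutral (grade 3).
#'
#' @param aspect_deg downslope compass aspect, degrees in \[0, 360).
#' @param bearing_to_lake_deg compass bearing from the cell to the lake
#'   centroid, degrees in \[0, 360).
#' @param near,far angular cutoffs in degrees (defaults 45 and 135).
#' @return integer grade in \{1, 3, 5\}.
#' @export
score_aspect <- function(aspect_deg, bearing_to_lake_deg, near = 45, far = 135) {
  if (any(aspect_deg < 0 | aspect_deg >= 360) ||
      any(bearing_to_lake_deg < 0 | bearing_to_lake_deg >= 360))
    stop("angles must lie in [0, 360)")
  d <- abs(aspect_deg - bearing_to_lake_deg)
  d <- pmin(d, 360 - d)
  ifelse(d <= near, 5L, ifelse(d <= far, 3L, 1L))
}

#' Grade soil permeability from texture class
#'
#' Low-permeability clay retains pollutants near the lake and carries the
#' highest hazard grade; highly permeable gravel the lowest.
#'
#' @param texture `"clay"`, `"sand"` or `"gravel"` (vectorised).
#' @return integer grade in \{5, 3, 1\}.
#' @export
score_permeability <- function(texture) {
  g <- .texture_grades[match(texture, names(.texture_grades))]
  if (anyNA(g)) stop("unknown soil texture: ",
                     paste(unique(texture[is.na(g)]), collapse = ", "))
  unname(g)
}

# -- rubric configuration -----------------------------------------------------

#' Default rubric configuration
#'
#' The tunable rubric choices and the bin/grade tables, as a plain list that
#' serialises to JSON for user editing (see [write_rubric_config()]).
#'
#' @return a named list.
#' @export
rubric_config <- function() {
  list(
    agricultural_scale = "extended_5bin",
    aspect_cutoffs = c(near = 45, far = 135),
    hazard_aggregation = "mode",
    nuclei_classes = 4L,
    combiner = "max",
    bins = list(
      irrigation_pct   = list(edges = c(10, 25, 50, 75), grades = 1:5),
      agricultural_pct = list(edges = c(20, 40, 60, 80), grades = 1:5),
      watershed_km2    = list(edges = c(38.85, 155.39, 388.47, 1942.35),
                              grades = 1:5),
      cover_pct        = list(edges = c(5, 20, 35, 50), grades = c(5, 4, 3, 2, 1)),
      slope_quartiles  = list(probs = c(0.25, 0.5, 0.75), grades = c(1, 3, 4, 5))
    ),
    categories = list(
      transport = as.list(.transport_grades),
      treatment = as.list(.treatment_grades),
      texture   = as.list(.texture_grades),
      sports    = as.list(.sports_grades),
      access    = as.list(.access_grades),
      infrastructure_within_50m = list(present = 4, absent = 0),
      industrial = list(present = 3, absent = 0),
      exploitation = list(mine_quarry_landfill = 5, exploitation_perimeter = 1,
                          none = 0)
    )
  )
}

#' Write / read the rubric configuration as JSON
#' @param config a list as returned by [rubric_config()].
#' @param path file path.
#' @return `read_rubric_config` returns the configuration list.
#' @export
write_rubric_config <- function(config = rubric_config(), path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rubric_config
#' @export
read_rubric_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$agricultural_scale) || is.null(cfg$bins))
    stop("not a rubric configuration file: ", path)
  cfg
}
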