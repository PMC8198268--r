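test_that("treatment-stage and wastewater grades follow the rubric", {
  expect_identical(score_treatment_stage("primary"), 3L)
  expect_identical(score_treatment_stage("secondary"), 2L)
  expect_identical(score_treatment_stage("tertiary"), 1L)
  expect_error(score_treatment_stage("quaternary"), "unknown")

  expect_identical(score_wastewater(character(0), FALSE), 0L)
  expect_identical(score_wastewater(c("primary", "secondary", "tertiary"), TRUE), 3L)
  expect_identical(score_wastewater("tertiary", TRUE), 1L)
})

test_that("recreation combines sports, access and infrastructure by maximum", {
  expect_identical(score_recreation("motorized", "by_car", TRUE), 5L)
  expect_identical(score_recreation("none", "pedestrian", FALSE), 2L)
  expect_identical(score_recreation("none", "prohibited", FALSE), 1L)
  expect_identical(score_recreation("none", "prohibited", TRUE), 4L)
  expect_error(score_recreation("jetski", "by_car", FALSE), "unknown")
})

test_that("percentage rubrics are left-closed with the printed bins", {
  expect_identical(score_irrigation(5), 1L)
  expect_identical(score_irrigation(10), 2L)   # boundary joins upper bin
  expect_identical(score_irrigation(60), 4L)
  expect_identical(score_irrigation(100), 5L)
  expect_error(score_irrigation(101), "range")

  expect_identical(score_agricultural_land(10, "printed_3bin"), 1L)
  expect_identical(score_agricultural_land(95, "extended_5bin"), 5L)
  expect_identical(score_agricultural_land(0), 1L)
  expect_identical(score_agricultural_land(0, "printed_3bin"), 1L)
  expect_identical(score_agricultural_land(50, "printed_3bin"), 3L)

  expect_identical(score_cover(60), 1L)
  expect_identical(score_cover(2), 5L)
  expect_identical(score_cover(35), 2L)        # boundary, left-closed

  expect_identical(score_watershed_size(10), 1L)
  expect_identical(score_watershed_size(500), 4L)
  expect_identical(score_watershed_size(38.85), 2L)
  expect_error(score_watershed_size(0), "positive")
})

test_that("every binned rubric is total on its domain", {
  set.seed(1)
  for (p in stats::runif(50, 0, 100)) {
    expect_true(score_irrigation(p) %in% 1:5)
    expect_true(score_agricultural_land(p) %in% 1:5)
    expect_true(score_cover(p) %in% 1:5)
  }
  for (a in stats::runif(50, 0.01, 5000))
    expect_true(score_watershed_size(a) %in% 1:5)
})

test_that("transport and industry take the worst applicable sub-grade", {
  expect_identical(score_transport(c("highway_or_ring", "national_road")), 5L)
  expect_identical(score_transport(character(0)), 0L)
  expect_identical(score_transport("unpaved_road"), 1L)
  expect_identical(score_transport(c("main_railway", "county_or_local_road")), 4L)
  expect_error(score_transport("donkey_track"), "unknown")

  expect_identical(score_industry(FALSE, "none"), 0L)
  expect_identical(score_industry(TRUE, "none"), 3L)
  expect_identical(score_industry(FALSE, "mine_quarry_landfill"), 5L)
  expect_identical(score_industry(TRUE, "exploitation_perimeter"), 3L)
})

test_that("max-combining rubrics are monotone under added categories", {
  cats <- names(wrastichi:::.transport_grades)
  set.seed(3)
  for (rep in 1:20) {
    base <- sample(cats, sample(0:3, 1))
    extra <- sample(cats, 1)
    expect_gte(score_transport(c(base, extra)), score_transport(base))
  }
  for (st in c("primary", "secondary", "tertiary")) {
    expect_gte(score_wastewater(c("tertiary", st), TRUE),
               score_wastewater("tertiary", TRUE))
  }
})

test_that("slope grading follows within-watershed quartiles", {
  set.seed(11)
  d <- stats::runif(400, 0, 30)
  expect_identical(score_slope(min(d), d), 1L)
  expect_identical(score_slope(max(d), d), 5L)
  # a value equal to the median sits in the upper (third-quartile) bin
  expect_identical(score_slope(stats::median(d), d), 4L)
  expect_error(score_slope(1, numeric(0)), "empty")

  # grading every cell splits the watershed into near-quarters
  g <- score_slope(d, d)
  expect_true(all(g %in% c(1L, 3L, 4L, 5L)))
  expect_true(all(abs(table(g) / length(d) - 0.25) < 0.01))
})

test_that("aspect grading measures exposure toward the lake", {
  expect_identical(score_aspect(90, 90), 5L)
  expect_identical(score_aspect(90, 270), 1L)
  expect_identical(score_aspect(0, 100), 3L)
  expect_identical(score_aspect(350, 10), 5L)  # wraps across north
  expect_error(score_aspect(400, 0), "360")
})

test_that("permeability grades invert soil texture permeability", {
  expect_identical(score_permeability("clay"), 5L)
  expect_identical(score_permeability("sand"), 3L)
  expect_identical(score_permeability("gravel"), 1L)
  expect_error(score_permeability("loam"), "unknown")
})

test_that("rubrics reproduce the reference grades from lake narratives", {
  lakes <- romanian_lakes()
  g <- function(name, col) lakes[lakes$name == name, col]

  # Merhei: no settlements or plants, no transport at all
  expect_identical(score_wastewater(character(0), FALSE), g("Merhei", "W"))
  expect_identical(score_transport(character(0)), g("Merhei", "T"))
  # Brates: impacted by all three treatment levels
  expect_identical(score_wastewater(c("primary", "secondary", "tertiary"), TRUE),
                   g("Brates", "W"))
  # Snagov: motorized sports allowed, reachable by county roads
  expect_identical(score_recreation("motorized", "by_car", TRUE), g("Snagov", "R"))
  # Lala: no car access, no infrastructure, no water sports
  expect_identical(score_recreation("none", "pedestrian", FALSE), g("Lala", "R"))
  # Potcoava: access prohibited
  expect_identical(score_recreation("none", "prohibited", FALSE),
                   g("Potcoava", "R"))
  # Siutghiol: motorway and European road cross the watershed
  expect_identical(score_transport(c("highway_or_ring", "national_road",
                                     "county_or_local_road")),
                   g("Siutghiol", "T"))
  # Vidraru: no industry or exploitation perimeters
  expect_identical(score_industry(FALSE, "none"), g("Vidraru", "I"))
  # Vacaresti: active industrial units
  expect_identical(score_industry(TRUE, "none"), g("Vacaresti", "I"))
  # Bratul Dunarea Veche: resource exploitation (quarry)
  expect_identical(score_industry(FALSE, "mine_quarry_landfill"),
                   g("Bratul Dunarea Veche", "I"))
  # Bezid: irrigation between 50 and 75 percent
  expect_identical(score_irrigation(62), g("Bezid", "a"))
  # Bistret and Brates: vegetation cover below 5 percent
  expect_identical(score_cover(3), g("Bistret", "C"))
})
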