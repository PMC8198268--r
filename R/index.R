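#' @title Index aggregation and degradation classification
#' @name index_core
#' @description The weighted aggregation of the seven pressure-indicator
#'   grades, the additive hazard index of the three terrain/soil grades, the
#'   three-type hazard classification and the per-type degradation bins.
NULL

.indicator_names <- c("W", "R", "A", "a", "S", "T", "I", "C")
.grade_ranges <- list(
  W = 0:4, R = 1:5, A = 1:5, a = 1:5, S = 1:5, T = 0:5, I = 0:5, C = 1:5
)

#' Indicator weight scheme
#'
#' The multipliers applied to the indicator grades in the aggregation sum.
#' The printed weights put 5 on "land used in agricultural activities" and 3
#' on "permanent irrigation"; that literal assignment misclassifies at least
#' one reference lake, while the transposed assignment reproduces all 30
#' reference states (see [calibrate_wrastic()]). The transposed assignment
#' is therefore the default.
#'
#' @param assignment `"transposed"` (default; wA = 3, wa = 5) or
#'   `"literal"` (wA = 5, wa = 3).
#' @param ... named overrides for individual weights (`W`, `R`, `A`, `a`,
#'   `S`, `T`, `I`, `C`), positive integers.
#' @return named integer vector of class `wrastic_weights`.
#' @export
wrastic_weights <- function(assignment = c("transposed", "literal"), ...) {
  assignment <- match.arg(assignment)
  w <- c(W = 3L, R = 3L, A = 3L, a = 5L, S = 1L, T = 1L, I = 4L, C = 1L)
  if (assignment == "literal") w[c("A", "a")] <- c(5L, 3L)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .indicator_names)
    if (length(bad)) stop("unknown weight name(s): ", paste(bad, collapse = ", "))
    w[names(dots)] <- as.integer(unlist(dots))
  }
  if (any(w <= 0)) stop("weights must be positive")
  structure(w, class = "wrastic_weights", assignment = assignment)
}

#' Hazard-type rule
#'
#' Maps the hazard sum (slope + aspect + permeability grades, range 3-15)
#' to one of three lake types by two monotone thresholds: sums up to `t1`
#' are type 1 (low pollutant-accumulation propensity), sums up to `t2`
#' type 2, larger sums type 3. The defaults (9, 12) are the simplest rule
#' in the feasible set found by [calibrate_wrastic()] against the bundled
#' reference evaluations.
#'
#' @param t1,t2 integer thresholds, `3 <= t1 < t2 <= 15`.
#' @return object of class `hi_type_rule`.
#' @export
hi_type_rule <- function(t1 = 9L, t2 = 12L) {
  t1 <- as.integer(t1); t2 <- as.integer(t2)
  if (!(t1 >= 3L && t1 < t2 && t2 <= 15L))
    stop("need 3 <= t1 < t2 <= 15")
  structure(list(t1 = t1, t2 = t2), class = "hi_type_rule")
}

#' Per-type degradation-state thresholds
#'
#' Upper bounds of the natural and semi-degraded classes for each hazard
#' type; the degraded class is the remainder up to (and, for robustness,
#' beyond) 100. Bounds tighten from type 1 to type 3: lakes physically
#' inclined to accumulate pollutants are classified more strictly.
#'
#' @return 3 x 2 integer matrix with rows `type1..type3` and columns
#'   `natural_max`, `semi_max`.
#' @export
class_thresholds <- function() {
  m <- rbind(type1 = c(30L, 63L), type2 = c(27L, 58L), type3 = c(21L, 44L))
  colnames(m) <- c("natural_max", "semi_max")
  m
}

.validate_grades <- function(scores) {
  for (nm in .indicator_names) {
    v <- scores[[nm]]
    if (is.null(v) || anyNA(v)) stop("missing grade for indicator ", nm)
    r <- .grade_ranges[[nm]]
    if (any(v != round(v)) || any(v < min(r)) || any(v > max(r)))
      stop("grade for ", nm, " out of range ", min(r), "-", max(r),
           ": ", paste(v[v < min(r) | v > max(r) | v != round(v)], collapse = ", "))
  }
  invisible(TRUE)
}

.validate_hazards <- function(h) {
  if (anyNA(h$slope) || any(!h$slope %in% 1:5))
    stop("slope grade must be in 1..5")
  if (anyNA(h$aspect) || any(!h$aspect %in% c(1L, 3L, 5L)))
    stop("aspect grade must be one of 1, 3, 5")
  if (anyNA(h$permeability) || any(!h$permeability %in% c(1L, 3L, 5L)))
    stop("permeability grade must be one of 1, 3, 5")
  invisible(TRUE)
}

#' Aggregate indicator grades into the index value
#'
#' Computes the weighted sum `sum(weight_i * grade_i)` over the eight
#' indicator grades (the agricultural indicator contributes two
#' sub-indicators, land use `A` and permanent irrigation `a`). Integer
#' arithmetic throughout, so results are exact.
#'
#' @param scores named list/row with integer grades `W`, `R`, `A`, `a`,
#'   `S`, `T`, `I`, `C`.
#' @param weights a [wrastic_weights()] scheme.
#' @return integer index value.
#' @export
compute_wrastic <- function(scores, weights = wrastic_weights()) {
  .validate_grades(scores)
  g <- vapply(.indicator_names, function(nm) as.integer(scores[[nm]][1L]),
              integer(1))
  sum(g * as.integer(weights[.indicator_names]))
}

#' Hazard sum
#'
#' @param slope,aspect,permeability integer hazard grades; alternatively
#'   pass a single list with those fields as `slope`.
#' @return integer sum in 3..15.
#' @export
hi_sum <- function(slope, aspect = NULL, permeability = NULL) {
  if (is.list(slope)) {
    h <- slope
  } else {
    h <- list(slope = slope, aspect = aspect, permeability = permeability)
  }
  .validate_hazards(h)
  as.integer(h$slope + h$aspect + h$permeability)
}

#' Assign the hazard type of a lake
#'
#' @param hazards list with `slope`, `aspect`, `permeability` grades, or an
#'   integer hazard sum.
#' @param rule a [hi_type_rule()].
#' @return integer type 1, 2 or 3.
#' @export
assign_hi_type <- function(hazards, rule = hi_type_rule()) {
  s <- if (is.list(hazards)) hi_sum(hazards) else as.integer(hazards)
  ifelse(s <= rule$t1, 1L, ifelse(s <= rule$t2, 2L, 3L))
}

#' Classify the degradation state
#'
#' Applies the per-type bins: values up to the type's natural bound are
#' `natural`, up to its semi-degraded bound `semi_degraded`, anything
#' larger `degraded` (values above 100, theoretically possible at extreme
#' grades, clamp into the degraded class).
#'
#' @param wrastic_value non-negative integer index value (vectorised).
#' @param hi_type integer type 1..3 (vectorised, recycled).
#' @param thresholds per-type bounds, see [class_thresholds()].
#' @return character vector: `"natural"`, `"semi_degraded"` or `"degraded"`.
#' @export
classify_state <- function(wrastic_value, hi_type,
                           thresholds = class_thresholds()) {
  if (any(wrastic_value < 0)) stop("index value must be non-negative")
  if (any(!hi_type %in% 1:3)) stop("hazard type must be 1, 2 or 3")
  n <- max(length(wrastic_value), length(hi_type))
  v <- rep_len(wrastic_value, n); ty <- rep_len(hi_type, n)
  nat <- thresholds[ty, "natural_max"]
  sem <- thresholds[ty, "semi_max"]
  ifelse(v <= nat, "natural", ifelse(v <= sem, "semi_degraded", "degraded"))
}

#' Evaluate a single lake
#'
#' Bundles the aggregation, hazard sum, hazard typing and classification
#' into one degradation result.
#'
#' @param scores indicator grades (named list, see [compute_wrastic()]).
#' @param hazards hazard grades (list with `slope`, `aspect`,
#'   `permeability`).
#' @param weights a [wrastic_weights()] scheme.
#' @param rule a [hi_type_rule()].
#' @param thresholds see [class_thresholds()].
#' @return list of class `degradation_result` with fields `wrastic_value`,
#'   `hi_sum`, `hi_type`, `state` (and `class_percentages` when produced by
#'   the geospatial engine).
#' @export
evaluate_lake <- function(scores, hazards, weights = wrastic_weights(),
                          rule = hi_type_rule(),
                          thresholds = class_thresholds()) {
  v <- compute_wrastic(scores, weights)
  s <- hi_sum(hazards)
  ty <- assign_hi_type(s, rule)
  structure(list(
    wrastic_value = v,
    hi_sum = s,
    hi_type = ty,
    state = classify_state(v, ty, thresholds),
    class_percentages = NULL
  ), class = "degradation_result")
}

#' @export
print.degradation_result <- function(x, ...) {
  cat("WRASTIC value:", x$wrastic_value,
      "| HI sum:", x$hi_sum, "(type", paste0(x$hi_type, ")"),
      "| state:", x$state, "\n")
  if (!is.null(x$class_percentages)) {
    cat("watershed class percentages:\n")
    print(round(x$class_percentages, 1))
  }
  invisible(x)
}
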