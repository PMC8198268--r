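#' @title Tabular and configuration input/output
#' @name io
NULL

.table_columns <- c("lake_id", "name", .indicator_names,
                    "slope", "aspect", "permeability")

#' Read a per-lake score table
#'
#' CSV with one row per lake; required columns are `lake_id`, `name`, the
#' eight indicator grades `W R A a S T I C` and the three hazard grades
#' `slope aspect permeability`. Non-integer grades are reported with their
#' row numbers.
#'
#' @param path CSV file path.
#' @return data frame of typed records.
#' @export
read_lake_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty table: ", path)
  miss <- setdiff(.table_columns, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (nm in c(.indicator_names, "slope", "aspect", "permeability")) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) | v != round(v))
    if (length(bad))
      stop("non-integer grade(s) in column ", nm, " at row(s) ",
           paste(bad, collapse = ", "))
    df[[nm]] <- as.integer(v)
  }
  df
}

#' The bundled 30-lake reference dataset
#'
#' The reference evaluation shipped with the package: 30 Romanian lakes
#' with their inventory data (area, county, origin, protection status,
#' morphologic unit), the eight indicator grades, the three hazard grades
#' and the published degradation state.
#'
#' @return data frame with 30 rows.
#' @export
romanian_lakes <- function() {
  path <- system.file("extdata", "romanian_lakes.csv", package = "wrastichi")
  if (path == "")
    path <- file.path("inst", "extdata", "romanian_lakes.csv")
  read_lake_table(path)
}

#' Write assessment results
#'
#' CSV output holds one row per lake (`wrastic_value`, `hi_sum`,
#' `hi_type`, `state`); GeoJSON output attaches the same fields (plus the
#' class percentages when present) as properties of each lake geometry.
#'
#' @param x a `wrastic` object (CSV) or a list of geospatial
#'   `degradation_result`s with a parallel list of lake features
#'   (GeoJSON, via `lakes`).
#' @param path output file.
#' @param format `"csv"` or `"geojson"`.
#' @param lakes for GeoJSON: list of lake [feature()]s parallel to `x`.
#' @return the path, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "geojson"),
                          lakes = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- if (inherits(x, "wrastic")) x$results else as.data.frame(x)
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(lakes)) stop("GeoJSON output needs the lake features")
  feats <- lapply(seq_along(x), function(i) {
    r <- x[[i]]
    f <- lakes[[i]]
    props <- list(wrastic_value = r$wrastic_value, hi_sum = r$hi_sum,
                  hi_type = r$hi_type, state = r$state)
    if (!is.null(r$class_percentages))
      props <- c(props, as.list(r$class_percentages))
    fj <- .feature_to_geojson(f, "lake")
    fj$properties <- c(fj$properties, props)
    fj
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the weight scheme, hazard-type rule, rubric configuration and
#' seed into one JSON-serialisable object whose defaults reproduce the
#' calibrated reference scheme.
#'
#' @param weights a [wrastic_weights()] scheme.
#' @param type_rule a [hi_type_rule()].
#' @param rubrics a [rubric_config()] list.
#' @param seed integer seed.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(weights = wrastic_weights(),
                       type_rule = hi_type_rule(),
                       rubrics = rubric_config(), seed = 1L) {
  structure(list(weights = as.list(unclass(weights)),
                 assignment = attr(weights, "assignment") %||% "transposed",
                 type_rule = list(t1 = type_rule$t1, t2 = type_rule$t2),
                 thresholds = {
                   m <- class_thresholds()
                   lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
                 },
                 rubrics = rubrics, seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param config a [run_config()].
#' @param path file path.
#' @return `read_run_config` returns a validated `run_config`-style list
#'   with reconstructed `wrastic_weights` and `hi_type_rule` objects.
#' @export
write_run_config <- function(config = run_config(), path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$weights) || is.null(cfg$type_rule))
    stop("not a run configuration file: ", path)
  w <- do.call(wrastic_weights,
               c(list(assignment = cfg$assignment %||% "transposed"),
                 as.list(cfg$weights)))
  list(weights = w,
       type_rule = hi_type_rule(cfg$type_rule$t1, cfg$type_rule$t2),
       rubrics = cfg$rubrics, seed = cfg$seed %||% 1L)
}
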