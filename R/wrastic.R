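#' Assess the degradation state of a set of lakes
#'
#' The central tabular entry point: takes one row of indicator and hazard
#' grades per lake, aggregates them with the weight scheme, assigns each
#' lake's hazard type and degradation state, and summarises counts overall
#' and by protection status and morphologic unit.
#'
#' @param data data frame with one row per lake. Required columns: the
#'   indicator grades `W`, `R`, `A`, `a`, `S`, `T`, `I`, `C` and the hazard
#'   grades `slope`, `aspect`, `permeability`. Optional columns used when
#'   present: `lake_id`, `name`, `protected` (yes/no or logical),
#'   `morphologic_unit`.
#' @param weights a [wrastic_weights()] scheme.
#' @param type_rule a [hi_type_rule()].
#' @param thresholds per-type state bounds, see [class_thresholds()].
#' @return an object of class `wrastic`: a list with `results` (per-lake
#'   data frame with `wrastic_value`, `hi_sum`, `hi_type`, `state`),
#'   `counts` (named vector over the three states), optional cross-tabs
#'   `by_protected` and `by_unit`, and the scheme used.
#' @examples
#' lakes <- romanian_lakes()
#' fit <- wrastic(lakes)
#' fit$counts
#' @export
wrastic <- function(data, weights = wrastic_weights(),
                    type_rule = hi_type_rule(),
                    thresholds = class_thresholds()) {
  need <- c(.indicator_names, "slope", "aspect", "permeability")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))

  n <- nrow(data)
  if (n == 0L) {
    res <- data.frame(wrastic_value = integer(0), hi_sum = integer(0),
                      hi_type = integer(0), state = character(0))
  } else {
    vals <- integer(n); his <- integer(n)
    for (i in seq_len(n)) {
      row <- as.list(data[i, , drop = FALSE])
      vals[i] <- tryCatch(compute_wrastic(row, weights),
                          error = function(e) stop("row ", i, ": ",
                                                   conditionMessage(e)))
      his[i] <- tryCatch(hi_sum(row$slope, row$aspect, row$permeability),
                         error = function(e) stop("row ", i, ": ",
                                                  conditionMessage(e)))
    }
    types <- assign_hi_type(his, type_rule)
    states <- classify_state(vals, types, thresholds)
    res <- data.frame(wrastic_value = vals, hi_sum = his, hi_type = types,
                      state = states, stringsAsFactors = FALSE)
  }
  for (nm in c("lake_id", "name")) if (nm %in% names(data))
    res[[nm]] <- data[[nm]]
  res <- res[, c(intersect(c("lake_id", "name"), names(res)),
                 "wrastic_value", "hi_sum", "hi_type", "state"), drop = FALSE]

  lev <- c("degraded", "semi_degraded", "natural")
  counts <- vapply(lev, function(s) sum(res$state == s), integer(1))

  by_protected <- NULL
  if ("protected" %in% names(data) && n > 0L) {
    p <- .as_flag(data$protected)
    by_protected <- table(protected = ifelse(p, "yes", "no"),
                          state = factor(res$state, levels = lev))
  }
  by_unit <- NULL
  if ("morphologic_unit" %in% names(data) && n > 0L) {
    by_unit <- table(unit = major_unit(data$morphologic_unit),
                     state = factor(res$state, levels = lev))
  }

  structure(list(results = res, counts = counts,
                 by_protected = by_protected, by_unit = by_unit,
                 weights = weights, type_rule = type_rule,
                 thresholds = thresholds, n = n),
            class = "wrastic")
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("yes", "true", "1", "y")
}

#' Map a specific morphologic unit name to its major geographic unit
#'
#' Keyword-based grouping used in the summary cross-tabulation
#' (mountains, hills, depressions, plains, plateaus, delta, corridors).
#'
#' @param unit character vector of unit names.
#' @return character vector of major unit labels.
#' @export
major_unit <- function(unit) {
  u <- tolower(unit)
  out <- rep("other", length(u))
  out[grepl("mountain", u)] <- "mountains"
  out[grepl("hill|sub-carpathian", u)] <- "hills"
  out[grepl("depression", u)] <- "depressions"
  out[grepl("plain", u)] <- "plains"
  out[grepl("plateau", u)] <- "plateaus"
  out[grepl("delta", u)] <- "delta"
  out[grepl("corridor", u)] <- "corridors"
  out
}

#' @export
print.wrastic <- function(x, ...) {
  cat("Lake ecosystem degradation assessment (", x$n, " lake",
      if (x$n != 1) "s", ")\n", sep = "")
  cat("  degraded: ", x$counts[["degraded"]],
      " | semi-degraded: ", x$counts[["semi_degraded"]],
      " | natural: ", x$counts[["natural"]], "\n", sep = "")
  invisible(x)
}

#' @export
summary.wrastic <- function(object, ...) {
  structure(list(counts = object$counts,
                 share_pct = round_half_up(100 * object$counts /
                                             max(object$n, 1L)),
                 by_protected = object$by_protected,
                 by_unit = object$by_unit,
                 results = object$results),
            class = "summary.wrastic")
}

#' @export
print.summary.wrastic <- function(x, ...) {
  cat("Degradation states:\n")
  print(data.frame(state = names(x$counts), lakes = as.integer(x$counts),
                   percent = as.integer(x$share_pct), row.names = NULL))
  if (!is.null(x$by_protected)) {
    cat("\nBy protection status:\n"); print(x$by_protected)
  }
  if (!is.null(x$by_unit)) {
    cat("\nBy major geographic unit:\n"); print(x$by_unit)
  }
  invisible(x)
}

#' @export
as.data.frame.wrastic <- function(x, ...) x$results

#' @export
weights.wrastic <- function(object, ...) object$weights

#' @export
plot.wrastic <- function(x, ...) {
  cols <- c(degraded = "firebrick", semi_degraded = "goldenrod",
            natural = "forestgreen")
  graphics::barplot(x$counts, col = cols[names(x$counts)],
                    names.arg = c("degraded", "semi-degraded", "natural"),
                    ylab = "lakes", main = "Degradation state of lakes", ...)
  invisible(x)
}

#' Round half away from zero
#'
#' Percentages in summaries are rounded half-up (e.g. 56.67 -> 57), matching
#' conventional reporting, rather than R's round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Calibrate the weight scheme and hazard-type rule against a reference
#'
#' The printed materials leave two choices under-specified: which of the two
#' agricultural sub-indicators carries weight 5, and how the hazard sum maps
#' to the three lake types. This exhaustively enumerates both choices -- the
#' two sub-weight assignments (optionally with user-supplied extra schemes)
#' crossed with every monotone two-threshold type rule -- and returns all
#' combinations that reproduce every reference state.
#'
#' @param reference data frame with indicator grades, hazard grades and a
#'   `state` column of printed degradation states (defaults to the bundled
#'   30-lake reference table).
#' @param assignments character vector of weight assignments to try
#'   (subset of `"transposed"`, `"literal"`).
#' @param thresholds see [class_thresholds()].
#' @return object of class `wrastic_calibration`: list with `feasible`
#'   (data frame of feasible scheme/rule combinations), `n_candidates`, and
#'   `best_infeasible` (the closest non-feasible candidate and its mismatch
#'   count). Errors if the feasible set is empty.
#' @export
calibrate_wrastic <- function(reference = romanian_lakes(),
                              assignments = c("transposed", "literal"),
                              thresholds = class_thresholds()) {
  if (!"state" %in% names(reference))
    stop("reference must contain a 'state' column of printed states")
  rules <- expand.grid(t1 = 3:14, t2 = 4:15)
  rules <- rules[rules$t1 < rules$t2, , drop = FALSE]
  rules <- rules[order(rules$t1, rules$t2), , drop = FALSE]

  cand <- expand.grid(assignment = assignments, idx = seq_len(nrow(rules)),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand$assignment[i]
    t1 <- rules$t1[cand$idx[i]]; t2 <- rules$t2[cand$idx[i]]
    fit <- wrastic(reference, weights = wrastic_weights(a),
                   type_rule = hi_type_rule(t1, t2), thresholds = thresholds)
    mism <- sum(fit$results$state != reference$state)
    rows[[i]] <- data.frame(assignment = a, t1 = t1, t2 = t2,
                            mismatches = mism, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  all <- all[order(all$mismatches, all$t1, all$t2, all$assignment), ]
  feasible <- all[all$mismatches == 0L, c("assignment", "t1", "t2")]
  rownames(feasible) <- NULL
  if (nrow(feasible) == 0L) {
    b <- all[1L, ]
    stop("no feasible scheme reproduces all reference states; closest: ",
         b$assignment, " weights with rule (", b$t1, ", ", b$t2, "), ",
         b$mismatches, " mismatch(es)")
  }
  structure(list(feasible = feasible, n_candidates = nrow(all),
                 scores = all,
                 default_feasible = any(feasible$assignment == "transposed" &
                                          feasible$t1 == 9L &
                                          feasible$t2 == 12L)),
            class = "wrastic_calibration")
}

#' @export
print.wrastic_calibration <- function(x, ...) {
  cat("Calibration over", x$n_candidates, "candidate scheme/rule combinations\n")
  cat("Feasible combinations (reproduce every reference state):",
      nrow(x$feasible), "\n")
  cat("Default scheme (transposed weights, rule 9/12) feasible:",
      x$default_feasible, "\n")
  by_a <- table(x$feasible$assignment)
  for (nm in names(by_a))
    cat("  ", nm, "weights:", by_a[[nm]], "feasible rule(s)\n")
  invisible(x)
}
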