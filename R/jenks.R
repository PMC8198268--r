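#' Jenks natural-breaks classification
#'
#' Computes the optimal partition of a one-dimensional sample into `k`
#' contiguous classes minimising the total within-class sum of squared
#' deviations (the Jenks/Fisher criterion), by exact dynamic programming.
#' This is the classification used to grade population aggregation nuclei.
#'
#' @param values numeric vector of finite observations.
#' @param k number of classes (>= 1).
#' @return numeric vector of `k - 1` interior break values, each the maximum
#'   of one class; a value `v` belongs to class `1 + sum(breaks < v)`.
#' @details Breaks are reported as class maxima, so classification is
#'   right-closed at each break: a value equal to a break falls in the lower
#'   class. For `k = 1` an empty numeric vector is returned. The result is
#'   deterministic for a fixed input.
#' @examples
#' jenks_breaks(c(1, 2, 3, 100, 101, 102), k = 2)
#' @export
jenks_breaks <- function(values, k) {
  if (!is.numeric(values) || length(values) == 0L)
    stop("'values' must be a non-empty numeric vector")
  if (any(!is.finite(values)))
    stop("'values' must be finite")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a single integer >= 1")
  k <- as.integer(k)
  n <- length(values)
  if (n < k)
    stop("need at least k values (", k, "), got ", n)
  ndist <- length(unique(values))
  if (ndist < k)
    stop("degenerate input: only ", ndist, " distinct value(s) for k = ", k,
         " classes")
  if (k == 1L) return(numeric(0))

  x <- sort(values)
  # prefix sums for O(1) within-class SSQ of x[i..j]
  cs  <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  ssq <- function(i, j) {
    s <- cs[j + 1L] - cs[i]
    q <- cs2[j + 1L] - cs2[i]
    q - s^2 / (j - i + 1L)
  }

  # D[j, m]: minimal cost of partitioning x[1..j] into m classes
  D <- matrix(Inf, nrow = n, ncol = k)
  B <- matrix(0L, nrow = n, ncol = k)   # start index of last class
  for (j in seq_len(n)) {
    D[j, 1L] <- ssq(1L, j)
    B[j, 1L] <- 1L
  }
  for (m in 2L:k) {
    for (j in m:n) {
      best <- Inf; besti <- m
      for (i in m:j) {
        cand <- D[i - 1L, m - 1L] + ssq(i, j)
        if (cand < best) { best <- cand; besti <- i }
      }
      D[j, m] <- best
      B[j, m] <- besti
    }
  }

  # backtrack class boundaries; break = max of each class but the last
  breaks <- numeric(k - 1L)
  j <- n
  for (m in k:2L) {
    i <- B[j, m]
    breaks[m - 1L] <- x[i - 1L]
    j <- i - 1L
  }
  breaks
}

#' Classify values against natural breaks
#'
#' @param x numeric values to classify.
#' @param breaks interior breaks as returned by [jenks_breaks()] (class
#'   maxima; right-closed).
#' @return integer class indices, 1-based.
#' @export
jenks_class <- function(x, breaks) {
  if (length(breaks) == 0L) return(rep(1L, length(x)))
  vapply(x, function(v) 1L + sum(breaks < v), integer(1))
}

#' Grade a population aggregation nucleus
#'
#' Grades a query value 1-4 by its Jenks natural-breaks class (k = 4) within
#' a reference distribution of population-density/aggregation values. Queries
#' outside the data range are clamped to it.
#'
#' @param distribution numeric reference sample (non-empty).
#' @param query value to grade.
#' @return integer grade in 1..4.
#' @export
score_aggregation_nuclei <- function(distribution, query) {
  if (length(distribution) == 0L)
    stop("empty distribution")
  br <- jenks_breaks(distribution, k = 4L)
  q <- min(max(query, min(distribution)), max(distribution))
  jenks_class(q, br)
}
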