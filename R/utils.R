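#' @importFrom stats cor dist qt quantile rnorm runif rpois rlnorm rbinom sd
#'   var prcomp setNames complete.cases binom.test cor.test
#' @importFrom utils head tail write.csv read.csv
#' @importFrom data.table data.table copy setorderv :=
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circular mean of calendar months
#'
#' Months live on a circle of circumference 12; the mean of December (12) and
#' February (2) is January (1), not July. Values are mapped to angles, averaged
#' as unit vectors (optionally weighted), and mapped back to the interval
#' `[1, 13)`.
#'
#' @param months numeric vector of (possibly fractional) calendar months.
#' @param weights optional non-negative weights, recycled to `length(months)`.
#' @return fractional calendar month in `[1, 13)`, or `NA` if no finite input
#'   or the resultant vector has zero length (perfectly dispersed input).
#' @export
circular_mean_month <- function(months, weights = NULL) {
  ok <- is.finite(months)
  if (!any(ok)) return(NA_real_)
  months <- months[ok]
  w <- if (is.null(weights)) rep(1, length(months)) else rep_len(weights, length(ok))[ok]
  if (sum(w) <= 0) return(NA_real_)
  ang <- (months - 1) / 12 * 2 * pi
  s <- sum(w * sin(ang)); c <- sum(w * cos(ang))
  if (sqrt(s^2 + c^2) / sum(w) < 1e-12) return(NA_real_)
  m <- atan2(s, c) / (2 * pi) * 12 + 1
  out <- (m - 1) %% 12
  if (out > 12 - 1e-9) out <- 0   # snap the wrap boundary to January
  out + 1
}

#' Signed minimal difference between two calendar months
#'
#' @param a,b months (possibly fractional).
#' @return signed difference `a - b` wrapped into `(-6, 6]`.
#' @export
circular_month_diff <- function(a, b) {
  d <- (a - b) %% 12
  ifelse(d > 6, d - 12, d)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two hard partitions of the same items.
#' Used to compare recovered fire-regime regions with planted ones.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
}
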