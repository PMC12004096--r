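#' Ordinary least-squares trend of one series with CI classification
#'
#' Fits `x = alpha + beta * (t - t[1])` by least squares, so `alpha` is the
#' fitted value at the start of the series and `beta` the rate of change
#' per time unit. The confidence interval on `beta` uses the t distribution
#' with `n - 2` degrees of freedom; the trend is classified `"increase"`
#' when the whole interval is above zero, `"decrease"` when below, `"none"`
#' otherwise. A perfect fit yields a zero-width interval and classification
#' by the sign of `beta`. Missing responses are dropped.
#'
#' @param y numeric response series.
#' @param t numeric time (strictly increasing where `y` is observed).
#' @param ci_level confidence level (default 0.80).
#' @return one-row data.frame: `alpha`, `beta`, `ci_lo`, `ci_hi`,
#'   `classification`, `n`.
#' @export
ols_trend <- function(y, t, ci_level = 0.80) {
  keep <- is.finite(y) & is.finite(t)
  y <- y[keep]; t <- t[keep]
  n <- length(y)
  if (n < 3) stop("ols_trend: need at least 3 observations")
  if (any(diff(t) <= 0)) stop("ols_trend: t must be strictly increasing")
  tt <- t - t[1]
  sxx <- sum((tt - mean(tt))^2)
  if (sxx == 0) stop("ols_trend: zero time variance")
  beta <- sum((tt - mean(tt)) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mean(tt)
  resid <- y - (alpha + beta * tt)
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  half <- qt((1 + ci_level) / 2, n - 2) * se
  lo <- beta - half; hi <- beta + half
  cls <- if (lo > 0) "increase" else if (hi < 0) "decrease" else "none"
  if (se == 0) cls <- if (beta > 0) "increase" else if (beta < 0) "decrease" else "none"
  data.frame(alpha = alpha, beta = beta, ci_lo = lo, ci_hi = hi,
             classification = cls, n = n)
}

# Unwrap a circular month series around its modal month so a linear trend
# is meaningful: each value is replaced by modal + signed circular
# difference from the modal month.
unwrap_months <- function(m) {
  ok <- is.finite(m)
  if (sum(ok) == 0) return(m)
  modal <- circular_mean_month(m[ok])
  modal + circular_month_diff(m, modal)
}

#' Per-cell trend fits for all fire variables
#'
#' Fits [ols_trend()] per cell: the five annual variables (fire count, size
#' quantiles, normalized burned area, season peak) on the year index, and
#' the period-level series (fire frequency and, when given, PC1 of the fire
#' PCA) on the period index. The season series is unwrapped around each
#' cell's circular modal month before fitting. Cells with fewer than 3
#' usable points for a variable are skipped with a message.
#'
#' @param annual a [regime_by_year()] table.
#' @param period_freq optional data.frame `cell_id`, `period_id`,
#'   `frequency_q99` (one row per cell-period).
#' @param period_pc1 optional data.frame `cell_id`, `period_id`, `pc1`
#'   (projected on the first-period axes).
#' @param ci_level confidence level (default 0.80).
#' @return data.frame of class `trend_fits`: `cell_id`, `variable`,
#'   `alpha`, `beta`, `ci_lo`, `ci_hi`, `classification`, `n`; attribute
#'   `summary` holds the per-variable fractions of cells classified
#'   increase / decrease / none.
#' @export
trend_maps <- function(annual, period_freq = NULL, period_pc1 = NULL,
                       ci_level = 0.80) {
  ann_vars <- c("n_fires", "size_q50_ha", "size_q99_ha", "burned_area_norm",
                "season_peak_month")
  rows <- list()
  skipped <- 0L
  fit_one <- function(cell, var, y, t) {
    keep <- is.finite(y)
    if (sum(keep) < 3) { skipped <<- skipped + 1L; return(NULL) }
    cbind(data.frame(cell_id = cell, variable = var),
          ols_trend(y[keep], t[keep], ci_level))
  }
  for (cell in unique(annual$cell_id)) {
    sub <- annual[annual$cell_id == cell, ]
    sub <- sub[order(sub$year_idx), ]
    for (v in ann_vars) {
      y <- sub[[v]]
      if (v == "season_peak_month") y <- unwrap_months(y)
      rows[[length(rows) + 1L]] <- fit_one(cell, v, y, sub$year_idx)
    }
  }
  if (!is.null(period_freq)) {
    for (cell in unique(period_freq$cell_id)) {
      sub <- period_freq[period_freq$cell_id == cell, ]
      sub <- sub[order(sub$period_id), ]
      rows[[length(rows) + 1L]] <-
        fit_one(cell, "frequency_q99", sub$frequency_q99, sub$period_id)
    }
  }
  if (!is.null(period_pc1)) {
    for (cell in unique(period_pc1$cell_id)) {
      sub <- period_pc1[period_pc1$cell_id == cell, ]
      sub <- sub[order(sub$period_id), ]
      rows[[length(rows) + 1L]] <-
        fit_one(cell, "pc1_fire", sub$pc1, sub$period_id)
    }
  }
  if (skipped) message(skipped, " cell-variable series skipped (< 3 points)")
  out <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(out, out$variable), function(d) {
    tab <- table(factor(d$classification,
                        c("increase", "decrease", "none"))) / nrow(d)
    data.frame(variable = d$variable[1], increase = tab[["increase"]],
               decrease = tab[["decrease"]], none = tab[["none"]])
  }))
  rownames(smry) <- NULL
  attr(out, "summary") <- smry
  class(out) <- c("trend_fits", "data.frame")
  out
}

#' Fire-activity change between two periods on a common component space
#'
#' Per-cell difference between the last-period PC1 score projected onto the
#' first-period fire PCA and the first-period score itself (positive =
#' activity increased), plus the cross-tabulation of region transitions.
#'
#' @param scores_p1 numeric vector of first-period PC1 scores, indexed by
#'   cell.
#' @param scores_pk_projected last-period PC1 scores projected with
#'   [project_onto()] on the first-period model (same cells, same order).
#' @param labels_p1,labels_pk optional region labels of the two periods for
#'   the transition table.
#' @return list of class `activity_change`: `delta` (per-cell), `mean_delta`,
#'   `transition` (first-period regions in rows; `NULL` without labels),
#'   `transition_frac` (rows normalized by first-period region size).
#' @export
activity_change <- function(scores_p1, scores_pk_projected,
                            labels_p1 = NULL, labels_pk = NULL) {
  if (length(scores_p1) != length(scores_pk_projected))
    stop("activity_change: unmatched cells")
  delta <- as.numeric(scores_pk_projected) - as.numeric(scores_p1)
  trans <- trans_frac <- NULL
  if (!is.null(labels_p1) && !is.null(labels_pk)) {
    stopifnot(length(labels_p1) == length(delta),
              length(labels_pk) == length(delta))
    trans <- table(first = labels_p1, last = labels_pk)
    trans_frac <- trans / rowSums(trans)
  }
  structure(list(delta = delta, mean_delta = mean(delta),
                 transition = trans, transition_frac = trans_frac),
            class = "activity_change")
}
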