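#' Dry-season months of a cell
#'
#' The dry season is the set of calendar months in which, on average over
#' the period, potential evapotranspiration strictly exceeds precipitation.
#'
#' @param precip,pet numeric vectors of monthly values, in month order
#'   starting at January and spanning whole years (length multiple of 12).
#' @return integer vector of calendar months (possibly empty).
#' @export
dry_season <- function(precip, pet) {
  stopifnot(length(precip) == length(pet), length(precip) %% 12 == 0,
            length(precip) >= 12)
  pm <- rowMeans(matrix(precip, nrow = 12))
  em <- rowMeans(matrix(pet, nrow = 12))
  which(em > pm)
}

# Zero-capped running water balance: cwd[k] = min(0, cwd[k-1] + d[k]),
# starting from cwd[0] = 0. `d` is precip - pet.
cwd_recursion <- function(d) {
  out <- numeric(length(d))
  acc <- 0
  for (k in seq_along(d)) {
    acc <- min(0, acc + d[k])
    out[k] <- acc
  }
  out
}

#' Climatological water deficit series
#'
#' The CWD is the cumulative difference between precipitation and potential
#' evapotranspiration, capped at zero (a surplus cannot be banked), computed
#' over 12-month cycles that restart at the period-mean wettest month of the
#' cell (ties take the earliest month). Leading months before the first
#' cycle start and a trailing incomplete cycle are dropped.
#'
#' @param precip,pet monthly series starting at January, whole years.
#' @return a 12 x n_cycles matrix of CWD values (\eqn{\le 0}); rows are
#'   calendar months January-December, columns complete cycles. Attribute
#'   `wettest_month` records the cycle-start month.
#' @export
cwd_series <- function(precip, pet) {
  stopifnot(length(precip) == length(pet), length(precip) %% 12 == 0)
  n_mo <- length(precip)
  if (n_mo < 12) stop("need at least one complete 12-month cycle")
  pm <- rowMeans(matrix(precip, nrow = 12))
  wettest <- which.max(pm)   # earliest tie
  start <- wettest           # first occurrence of the wettest month
  n_cycles <- (n_mo - start + 1L) %/% 12L
  if (n_cycles < 1L) stop("series too short for one cycle from the wettest month")
  out <- matrix(NA_real_, 12, n_cycles)
  d <- precip - pet
  for (cy in seq_len(n_cycles)) {
    idx <- start + (cy - 1L) * 12L + 0:11
    cwd <- cwd_recursion(d[idx])
    cal <- ((idx - 1L) %% 12L) + 1L
    out[cal, cy] <- cwd
  }
  attr(out, "wettest_month") <- wettest
  out
}

#' Month of the most negative mean climatological water deficit
#'
#' @param cwd a 12 x cycles matrix from [cwd_series()].
#' @return integer calendar month (ties take the earliest); `NA` with
#'   attribute `no_dry_season = TRUE` when the mean CWD is zero everywhere.
#' @export
peak_dry_season <- function(cwd) {
  stopifnot(nrow(cwd) == 12)
  m <- rowMeans(cwd)
  if (all(m == 0)) return(structure(NA_integer_, no_dry_season = TRUE))
  which.min(m)
}

#' Per-cell climate summary over a period
#'
#' Derives, for every cell of a [simulate_climate()]-style series (columns
#' `cell_id`, `year`, `month`, `temp`, `precip`, `pet`): the pooled-month
#' mean annual temperature, the dry-season temperature, the mean total
#' annual precipitation, the mean total dry-season precipitation, the
#' dry-season month set, the monthly mean CWD and the peak of the dry
#' season. One dry-season set is computed per cell-period and applied to
#' every year of the period.
#'
#' @param series a `climate_series` data.frame.
#' @return data.frame of class `climate_summary`, one row per cell:
#'   `cell_id`, `t_annual`, `t_dry`, `p_annual`, `p_dry`,
#'   `peak_dry_season`, `n_dry_months`; attributes `dry_months` (list) and
#'   `cwd_monthly` (cells x 12 matrix).
#' @export
climate_summary <- function(series) {
  stopifnot(all(c("cell_id", "year", "month", "temp", "precip", "pet")
                %in% names(series)))
  series <- series[order(series$cell_id, series$year, series$month), ]
  cells <- unique(series$cell_id)
  rows <- vector("list", length(cells))
  dry_list <- vector("list", length(cells))
  cwd_mat <- matrix(NA_real_, length(cells), 12)
  for (i in seq_along(cells)) {
    s <- series[series$cell_id == cells[i], ]
    dm <- dry_season(s$precip, s$pet)
    cwd <- cwd_series(s$precip, s$pet)
    cwd_mean <- rowMeans(cwd)
    pk <- peak_dry_season(cwd)
    years <- length(s$precip) / 12
    rows[[i]] <- data.frame(
      cell_id = cells[i],
      t_annual = mean(s$temp),
      t_dry = if (length(dm)) mean(s$temp[s$month %in% dm]) else NA_real_,
      p_annual = sum(s$precip) / years,
      p_dry = if (length(dm)) sum(s$precip[s$month %in% dm]) / years else 0,
      peak_dry_season = as.integer(pk),
      n_dry_months = length(dm))
    dry_list[[i]] <- dm
    cwd_mat[i, ] <- cwd_mean
  }
  out <- do.call(rbind, rows)
  attr(out, "dry_months") <- dry_list
  attr(out, "cwd_monthly") <- cwd_mat
  class(out) <- c("climate_summary", "data.frame")
  out
}
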