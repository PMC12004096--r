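#' Quantile of a smoothed empirical cumulative distribution function
#'
#' The sECDF replaces the staircase ECDF by linear interpolation between
#' the distinct observed values, each placed at the midpoint of its
#' cumulative-probability step: a distinct value `v` with multiplicity `c`
#' out of `n` sits at `(#\{x < v\} + c/2) / n`. The result is a continuous,
#' invertible CDF whose inverse at `q` is the returned quantile. For an
#' all-distinct sample this reduces to interpolation at the plotting
#' positions `(i - 0.5)/n`; for tied (e.g. integer-count) data the quantile
#' responds continuously to the composition instead of jumping between
#' integers. Below the first and above the last position the sample
#' extremes are returned, so the result stays within the data range. With
#' `smoothing = "none"` the plain step-ECDF inverse (a sample order
#' statistic) is returned.
#'
#' @param values non-empty numeric vector.
#' @param q quantile level in (0, 1).
#' @param smoothing `"linear"` (default) or `"none"`.
#' @return the q-quantile of the (smoothed) ECDF.
#' @examples
#' secdf_quantile(1:100, 0.5)  # 50.5
#' @export
secdf_quantile <- function(values, q, smoothing = c("linear", "none")) {
  smoothing <- match.arg(smoothing)
  values <- values[is.finite(values)]
  if (!length(values)) stop("secdf_quantile: empty input")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (smoothing == "none") {
    x <- sort(values)
    return(x[ceiling(q * length(x))])
  }
  weighted_secdf_quantile(values, rep(1, length(values)), q)
}

# Weighted sECDF quantile: point masses w_i at x_i; ties aggregated, each
# distinct value placed at the midpoint of its cumulative-weight step,
# linear interpolation in between. Reduces to secdf_quantile for unit
# weights.
weighted_secdf_quantile <- function(x, w, q) {
  keep <- is.finite(x) & is.finite(w) & w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) return(NA_real_)
  w <- vapply(split(w, x), sum, numeric(1))
  v <- sort(unique(x))
  if (length(v) == 1L) return(v)
  p <- (cumsum(w) - w / 2) / sum(w)
  if (q <= p[1]) return(v[1])
  if (q >= p[length(p)]) return(v[length(v)])
  stats::approx(p, v, xout = q, ties = "ordered")$y
}

#' Modal burning month defining a cell's fire-year
#'
#' The fire-year of a cell is the 12-month window that places the month with
#' the highest mean burned area at position 6 of 0-11, so that seasonality
#' statistics are comparable between cells whose fire seasons peak at
#' different times of the calendar year. Ties take the earliest month.
#'
#' @param monthly_burned numeric 12-vector of mean burned area per calendar
#'   month (January first).
#' @return integer modal month 1-12, or `NA` if nothing burned.
#' @export
fire_year_offset <- function(monthly_burned) {
  stopifnot(length(monthly_burned) == 12, all(monthly_burned >= 0 | is.na(monthly_burned)))
  if (all(is.na(monthly_burned)) || sum(monthly_burned, na.rm = TRUE) == 0)
    return(NA_integer_)
  which.max(monthly_burned)  # which.max takes the earliest tie
}

#' Peak of the fire season (sECDF median in the fire-year frame)
#'
#' Reorders calendar months into the cell's fire-year frame (modal month at
#' position 6 of 0-11), takes the burned-area-weighted sECDF median of the
#' month positions, and maps the result back to a fractional calendar month.
#' The statistic is circular: rotating all burning by +k months shifts the
#' result by exactly +k (mod 12).
#'
#' @param monthly_burned numeric 12-vector (or 12 x years matrix, summed over
#'   years) of burned area per calendar month.
#' @param fire_year modal month from [fire_year_offset()]; computed when
#'   missing.
#' @return fractional calendar month in `[1, 13)`, `NA` if nothing burned.
#' @export
season_peak <- function(monthly_burned, fire_year = NULL) {
  if (is.matrix(monthly_burned)) {
    stopifnot(nrow(monthly_burned) == 12)
    monthly_burned <- rowSums(monthly_burned)
  }
  stopifnot(length(monthly_burned) == 12)
  if (sum(monthly_burned, na.rm = TRUE) == 0) return(NA_real_)
  if (is.null(fire_year)) fire_year <- fire_year_offset(monthly_burned)
  if (is.na(fire_year)) return(NA_real_)
  fy_start <- ((fire_year - 1L - 6L) %% 12L) + 1L   # month at position 0
  pos <- ((1:12) - fy_start) %% 12                  # position of each month
  med_pos <- weighted_secdf_quantile(pos, monthly_burned, 0.5)
  ((fy_start - 1 + med_pos) %% 12) + 1
}

#' Per-cell, per-period fire context from a cube and its events
#'
#' Collects, for one grid cell, everything [compute_regime()] needs: the mean
#' flammable area, the monthly burned-area table and the per-pixel counts of
#' years burned (including zeros for never-burned pixels).
#'
#' @param cube a `burned_cube`.
#' @param cell_id cell id.
#' @param flammable_area_ha mean flammable area of the cell over the period
#'   (ha); defaults to the full cell area.
#' @param years_idx indices of the cube's year layers forming the period
#'   (default: all).
#' @return list of class `cell_period_context`.
#' @export
cell_period_context <- function(cube, cell_id,
                                flammable_area_ha = NULL,
                                years_idx = seq_len(cube$years)) {
  g <- cube$grid
  if (is.null(flammable_area_ha)) flammable_area_ha <- g$cell_area_ha
  rc <- cell_rowcol(g, cell_id)
  pr <- (rc[1] - 1L) * g$pixels_per_cell + seq_len(g$pixels_per_cell)
  pc <- (rc[2] - 1L) * g$pixels_per_cell + seq_len(g$pixels_per_cell)
  block <- cube$data[pr, pc, years_idx, drop = FALSE]
  monthly <- matrix(0, 12, length(years_idx))
  for (k in seq_along(years_idx)) {
    tab <- tabulate(block[, , k], nbins = 12)
    monthly[, k] <- tab * g$pixel_area_ha
  }
  burn_counts <- as.vector(rowSums(
    matrix(block > 0, nrow = length(pr) * length(pc))))
  structure(list(cell_id = cell_id, flammable_area_ha = flammable_area_ha,
                 monthly_burned = monthly, pixel_burn_counts = burn_counts,
                 n_years = length(years_idx)),
            class = "cell_period_context")
}

#' Six fire-regime variables for one cell and period
#'
#' Computes, for a grid cell over a multi-year period: the number of fires
#' per `norm_area_ha` of flammable area; the 50th and 99th sECDF quantiles
#' of the sizes of events intersecting the cell (each event enters with its
#' full area, not the within-cell clip); the burned area (sum of burned
#' pixel area over all years, within-cell) divided by flammable area; the
#' fire frequency (99th sECDF quantile of per-pixel years-burned counts,
#' zeros included); and the fire-season peak on the fire-year frame.
#'
#' @param ctx a `cell_period_context`.
#' @param event_areas_ha numeric vector of full areas of the events
#'   intersecting the cell (empty if none).
#' @param norm_area_ha normalization constant for the fire count (default
#'   1e4 ha = 100 km2 of flammable area).
#' @return one-row data.frame with `cell_id`, `n_fires`, `size_q50_ha`,
#'   `size_q99_ha`, `burned_area_norm`, `frequency_q99`,
#'   `season_peak_month`, `imputed = FALSE`; or with `imputed = NA` fields
#'   when the cell saw no events (route to [impute_no_fire()]).
#' @export
compute_regime <- function(ctx, event_areas_ha, norm_area_ha = 1e4) {
  stopifnot(inherits(ctx, "cell_period_context"))
  burned_ha <- sum(ctx$monthly_burned)
  if (ctx$flammable_area_ha <= 0 && burned_ha > 0)
    stop(sprintf("cell %d: burning present but flammable area is zero",
                 ctx$cell_id))
  if (!length(event_areas_ha)) {
    return(data.frame(cell_id = ctx$cell_id, n_fires = NA_real_,
                      size_q50_ha = NA_real_, size_q99_ha = NA_real_,
                      burned_area_norm = NA_real_, frequency_q99 = NA_real_,
                      season_peak_month = NA_real_, imputed = NA))
  }
  data.frame(
    cell_id = ctx$cell_id,
    n_fires = length(event_areas_ha) / ctx$flammable_area_ha * norm_area_ha,
    size_q50_ha = secdf_quantile(event_areas_ha, 0.5),
    size_q99_ha = secdf_quantile(event_areas_ha, 0.99),
    burned_area_norm = burned_ha / ctx$flammable_area_ha,
    frequency_q99 = secdf_quantile(ctx$pixel_burn_counts, 0.99),
    season_peak_month = season_peak(ctx$monthly_burned),
    imputed = FALSE)
}

#' Impute the fire regime of a cell with no fires
#'
#' Cells with no events in a period still need values for clustering: sizes
#' and raw burned area are set to the minimum fire size (`min_area_ha`,
#' default 3 ha; burned area then normalized by flammable area), frequency
#' to 1, the fire count to 1 (then normalized like real counts), and the
#' season peak to the circular mean of the season peaks of the 8
#' neighbouring cells, expanding to the next ring when the whole
#' neighbourhood is undefined.
#'
#' @param grid a `fire_grid`.
#' @param cell_id cell to impute.
#' @param neighbor_season numeric vector over all cells of season peaks
#'   (NA where undefined).
#' @param flammable_area_ha the cell's flammable area (ha).
#' @param min_area_ha minimum fire size (ha).
#' @param norm_area_ha fire-count normalization constant (ha).
#' @return one-row data.frame as [compute_regime()], `imputed = TRUE`.
#' @export
impute_no_fire <- function(grid, cell_id, neighbor_season,
                           flammable_area_ha, min_area_ha = 3,
                           norm_area_ha = 1e4) {
  season <- NA_real_
  for (ring in seq_len(max(grid$n_rows, grid$n_cols) - 1L)) {
    nb <- cell_neighbors(grid, cell_id, ring)
    vals <- neighbor_season[nb]
    if (any(is.finite(vals))) {
      if (ring > 1L)
        message(sprintf("cell %d: seasonality imputed from ring %d",
                        cell_id, ring))
      season <- circular_mean_month(vals)
      break
    }
  }
  data.frame(cell_id = cell_id,
             n_fires = 1 / flammable_area_ha * norm_area_ha,
             size_q50_ha = min_area_ha, size_q99_ha = min_area_ha,
             burned_area_norm = min_area_ha / flammable_area_ha,
             frequency_q99 = 1,
             season_peak_month = season, imputed = TRUE)
}

# Map each event to the set of cells it intersects, via its pixel records.
events_by_cell <- function(events, grid) {
  px <- events$pixels[!is.na(events$pixels$event_id), , drop = FALSE]
  if (!nrow(px))
    return(data.frame(cell_id = integer(), event_id = integer(),
                      area_ha = numeric()))
  cell <- cell_of_pixel(grid, px$px_row, px$px_col)
  dt <- unique(data.table::data.table(cell_id = cell,
                                      event_id = px$event_id))
  dt$area_ha <- events$events$area_ha[match(dt$event_id,
                                            events$events$event_id)]
  as.data.frame(dt)
}

#' Fire-regime table for every cell of the grid
#'
#' Runs [compute_regime()] for every cell over one period and applies the
#' no-fire imputation. Events intersecting several cells are counted once
#' per intersected cell with their full area; within-cell burned area uses
#' pixel locations only.
#'
#' @param cube a `burned_cube`.
#' @param events `fire_events` from [label_events()] on that cube.
#' @param flammable_area_ha per-cell flammable areas (ha), a vector indexed
#'   by cell id; defaults to the full cell area everywhere.
#' @param years_idx cube year layers forming the period (default all).
#' @param min_area_ha,norm_area_ha see [impute_no_fire()] /
#'   [compute_regime()].
#' @param period_id label stored in the result (default 1).
#' @return data.frame of class `fire_regimes`, one row per cell, columns as
#'   [compute_regime()] plus `period_id`.
#' @export
regime_table <- function(cube, events, flammable_area_ha = NULL,
                         years_idx = seq_len(cube$years),
                         min_area_ha = 3, norm_area_ha = 1e4,
                         period_id = 1L) {
  g <- cube$grid
  if (is.null(flammable_area_ha))
    flammable_area_ha <- rep(g$cell_area_ha, g$n_cells)
  stopifnot(length(flammable_area_ha) == g$n_cells)
  ebc <- events_by_cell(events, g)
  # restrict to events whose span starts in the period's months
  t_lo <- (min(years_idx) - 1L) * 12L; t_hi <- max(years_idx) * 12L - 1L
  ev_in <- events$events$event_id[events$events$t_start >= t_lo &
                                    events$events$t_start <= t_hi]
  ebc <- ebc[ebc$event_id %in% ev_in, , drop = FALSE]
  sizes_by_cell <- split(ebc$area_ha, ebc$cell_id)
  rows <- vector("list", g$n_cells)
  for (cell in seq_len(g$n_cells)) {
    ctx <- cell_period_context(cube, cell, flammable_area_ha[cell], years_idx)
    rows[[cell]] <- compute_regime(
      ctx, sizes_by_cell[[as.character(cell)]] %||% numeric(0), norm_area_ha)
  }
  out <- do.call(rbind, rows)
  # no-fire imputation, seasonality from neighbours of the first pass
  season <- out$season_peak_month
  todo <- which(is.na(out$imputed))
  for (cell in todo) {
    out[cell, ] <- impute_no_fire(g, cell, season, flammable_area_ha[cell],
                                  min_area_ha, norm_area_ha)
  }
  out$period_id <- period_id
  class(out) <- c("fire_regimes", "data.frame")
  out
}

#' Annual fire-regime series for trend analysis
#'
#' Computes, per cell and single year, the five annually defined variables
#' (fire count, size quantiles, normalized burned area, season peak); fire
#' frequency is period-level and not produced here. Years with no events in
#' a cell get the same imputation as [regime_table()] except the season,
#' which is left `NA` (trend fits drop missing years).
#'
#' @inheritParams regime_table
#' @return data.frame with `cell_id`, `year_idx`, the five variables and
#'   `imputed`.
#' @export
regime_by_year <- function(cube, events, flammable_area_ha = NULL,
                           min_area_ha = 3, norm_area_ha = 1e4) {
  g <- cube$grid
  if (is.null(flammable_area_ha))
    flammable_area_ha <- rep(g$cell_area_ha, g$n_cells)
  out <- vector("list", cube$years)
  for (y in seq_len(cube$years)) {
    tab <- regime_table(cube, events, flammable_area_ha, years_idx = y,
                        min_area_ha = min_area_ha,
                        norm_area_ha = norm_area_ha, period_id = y)
    tab$season_peak_month[tab$imputed] <- NA_real_
    tab$year_idx <- y
    tab$frequency_q99 <- NULL
    out[[y]] <- as.data.frame(tab)
  }
  do.call(rbind, out)
}
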