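#' Specify one planted fire-regime region
#'
#' A region is a spatially contiguous set of grid cells sharing one fire
#' regime: an event rate, a lognormal event-size distribution, a seasonal
#' peak month with a circular concentration, and a propensity of burned
#' pixels to re-burn in later years.
#'
#' @param region_id integer id.
#' @param cells integer vector of row-major cell ids; must induce a connected
#'   subgraph under queen contiguity.
#' @param event_rate expected fire events per cell per year (>= 0).
#' @param size_log_median natural log of the median event size in hectares.
#' @param size_log_sd lognormal sd on the log scale (> 0).
#' @param peak_month calendar month 1-12 at which the fire season peaks.
#' @param season_concentration circular concentration (>= 0); event months are
#'   wrapped-normal around `peak_month` with sd `3 / sqrt(1 + concentration)`
#'   months, so 0 is diffuse and large values are sharply peaked.
#' @param reburn_propensity probability in `[0, 1]` that a pixel burned in an
#'   earlier year is admissible fuel for a later event.
#' @param grid optional `fire_grid`; when given, contiguity of `cells` is
#'   checked immediately.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(region_id, cells, event_rate, size_log_median,
                        size_log_sd, peak_month,
                        season_concentration = 2.5,
                        reburn_propensity = 0.2,
                        grid = NULL) {
  stopifnot(length(cells) >= 1, event_rate >= 0, is.finite(event_rate),
            is.finite(size_log_median), size_log_sd > 0,
            peak_month %in% 1:12, season_concentration >= 0,
            reburn_propensity >= 0, reburn_propensity <= 1)
  spec <- structure(list(
    region_id = as.integer(region_id), cells = as.integer(sort(cells)),
    event_rate = event_rate, size_log_median = size_log_median,
    size_log_sd = size_log_sd, peak_month = as.integer(peak_month),
    season_concentration = season_concentration,
    reburn_propensity = reburn_propensity), class = "region_spec")
  if (!is.null(grid) && !region_is_connected(spec, grid))
    stop(sprintf("region %d cells are not connected under queen contiguity",
                 spec$region_id), call. = FALSE)
  spec
}

region_is_connected <- function(spec, grid) {
  cg <- build_contiguity(grid, "queen")
  keep <- cg$edges[, 1] %in% spec$cells & cg$edges[, 2] %in% spec$cells
  g <- igraph::graph_from_edgelist(
    matrix(as.character(cg$edges[keep, , drop = FALSE]), ncol = 2),
    directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(spec$cells),
                                    igraph::V(g)$name))
  igraph::count_components(g) == 1L
}

check_region_partition <- function(grid, regions) {
  all_cells <- sort(unname(unlist(lapply(regions, `[[`, "cells"))))
  if (anyDuplicated(all_cells))
    stop("region cell sets overlap", call. = FALSE)
  if (!identical(all_cells, seq_len(grid$n_cells)))
    stop("region cell sets do not cover the grid", call. = FALSE)
  invisible(TRUE)
}

#' Default synthetic landscape: four planted fire-regime regions
#'
#' Four contiguous quadrants of the grid emulating the canonical regime
#' taxonomy of tropical-savanna fire mosaics: a high-fire-activity region
#' (frequent, large fires; south-east quadrant), an intermediate one
#' (south-west), a low-activity one (north-west), and a northern
#' late-season region of small but numerous fires peaking two months later
#' (October vs August) with a concentrated season (north-east). The layout
#' puts the low-activity region diagonal to the high-activity one so that
#' their contrast is not blurred by adjacency. Rates are events per cell
#' per year; sizes are lognormal medians in hectares; reburn propensities
#' are graded with activity so the years-burned distribution spreads in the
#' active regimes and stays at one burn in the low regime. These defaults
#' are chosen for separability and per-cell estimator stability of the
#' planted regimes, not landscape realism.
#'
#' @param grid a `fire_grid` with even-ish `n_rows`, `n_cols` (quadrants are
#'   formed by splitting rows and columns at the midpoint).
#' @return list of four `region_spec` objects: high, intermediate, low,
#'   late-season (region ids 1-4).
#' @export
default_regions <- function(grid) {
  rc <- cell_rowcol(grid, seq_len(grid$n_cells))
  top <- rc[, 1] <= ceiling(grid$n_rows / 2)
  left <- rc[, 2] <= ceiling(grid$n_cols / 2)
  list(
    high = region_spec(1L, which(!top & !left), event_rate = 3.2,
                       size_log_median = log(13), size_log_sd = 0.25,
                       peak_month = 8L, season_concentration = 2.5,
                       reburn_propensity = 0.55),
    intermediate = region_spec(2L, which(!top & left), event_rate = 1.8,
                               size_log_median = log(8), size_log_sd = 0.25,
                               peak_month = 8L, season_concentration = 2.5,
                               reburn_propensity = 0.5),
    low = region_spec(3L, which(top & left), event_rate = 1.5,
                      size_log_median = log(5), size_log_sd = 0.25,
                      peak_month = 8L, season_concentration = 5,
                      reburn_propensity = 0.5),
    late_season = region_spec(4L, which(top & !left), event_rate = 3.0,
                              size_log_median = log(5.5), size_log_sd = 0.25,
                              peak_month = 10L, season_concentration = 8,
                              reburn_propensity = 0.7)
  )
}

# Draw an event month from a wrapped normal centred on peak_month.
draw_event_month <- function(n, peak_month, concentration) {
  sd <- 3 / sqrt(1 + concentration)
  m <- round(rnorm(n, peak_month, sd))
  ((m - 1) %% 12) + 1L
}

# Grow a connected pixel blob of `size_px` pixels by stochastic breadth-first
# dilation from `seed_px` within the admissible mask (TRUE = available).
# Returns linear pixel indices (column-major over px_rows x px_cols).
grow_blob <- function(seed_px, size_px, admissible, px_rows, px_cols) {
  if (!admissible[seed_px]) return(integer(0))
  taken <- seed_px
  admissible[seed_px] <- FALSE
  frontier <- seed_px
  while (length(taken) < size_px) {
    # 4-neighbour dilation of the current frontier, clipped to the lattice
    r <- (frontier - 1L) %% px_rows + 1L
    c <- (frontier - 1L) %/% px_rows + 1L
    nb <- c(frontier[r > 1L] - 1L, frontier[r < px_rows] + 1L,
            frontier[c > 1L] - px_rows, frontier[c < px_cols] + px_rows)
    nb <- unique(nb[admissible[nb]])
    if (!length(nb)) break
    # accept a random fraction of the frontier each round: irregular edges
    want <- size_px - length(taken)
    k <- min(want, max(1L, round(runif(1, 0.3, 0.9) * length(nb))))
    acc <- if (k >= length(nb)) nb else sample(nb, k)
    admissible[acc] <- FALSE
    taken <- c(taken, acc)
    frontier <- acc
  }
  taken
}

#' Simulate a month-coded burned-area cube with planted fire events
#'
#' For each region and year the number of events is Poisson with mean
#' `event_rate * n_cells`; each event draws a lognormal target size, a
#' wrapped-normal month around the region's seasonal peak, a uniform seed
#' pixel inside the region, and grows as a connected blob by stochastic
#' breadth-first dilation. Growth is not confined to the seeding region:
#' fires ignited near a regime boundary spread across it, as real fires do,
#' which also keeps boundary cells statistically comparable to interior
#' cells (confined growth would starve them of fire). With probability
#' `span_prob` an event's pixels are split between its month and the next
#' (consecutive) month, emulating fires mapped across a month boundary.
#' Pixels already burned the same year are never re-used; pixels burned
#' within the last `recovery_years` years are admissible only with the
#' igniting region's `reburn_propensity` (fuel takes a wet season or two to
#' recover), and older burns are fully admissible again, so the simulated
#' regimes are stationary in time. Every burned pixel in the cube belongs
#' to exactly one planted event.
#'
#' Each region is simulated independently on its own ghost-padded fuel bed:
#' the region's pixel mask dilated by `margin_px` in every direction (also
#' beyond the domain edge). Seed counts are scaled by the padded area and
#' events are cropped to the region's own cells afterwards, so every cell —
#' at a regime boundary, at the domain edge, or interior — experiences the
#' same homogeneous event climate of its regime, with no artificial fire
#' deficit at borders and no contamination from neighbouring regimes.
#'
#' @param grid a `fire_grid`.
#' @param regions list of `region_spec` partitioning the grid.
#' @param years number of annual layers (>= 1).
#' @param seed RNG seed; identical seeds give bit-identical cubes.
#' @param year0 first calendar year (default 1985).
#' @param span_prob probability an event spans two consecutive months.
#' @param margin_px width of the ghost margin in pixels (default half a
#'   cell).
#' @param recovery_years years a burned pixel stays reburn-gated before its
#'   fuel fully recovers (default 2).
#' @return a list of class `burned_cube` with elements `data` (integer array
#'   `px_rows x px_cols x years`; 0 = unburned, 1-12 = burn month), `grid`,
#'   `year0`, `years`, and `truth` (a `synthetic_truth`: `labels` cell ->
#'   region, `events` data.frame of planted events with their within-domain
#'   `pixel_count`/`area_ha` and drawn `size_px_target`, `pixels` data.frame
#'   of planted pixel-burn records with their event id; events lying wholly
#'   in the ghost margin are not recorded).
#' @export
simulate_burned_cube <- function(grid, regions, years, seed,
                                 year0 = 1985L, span_prob = 0.3,
                                 margin_px = grid$pixels_per_cell %/% 2L,
                                 recovery_years = 2L) {
  stopifnot(inherits(grid, "fire_grid"), years >= 1, margin_px >= 0,
            recovery_years >= 0)
  check_region_partition(grid, regions)
  set.seed(seed)
  PR <- grid$px_rows; PC <- grid$px_cols; ppc <- grid$pixels_per_cell
  mg <- as.integer(margin_px)
  PRe <- PR + 2L * mg; PCe <- PC + 2L * mg
  cube <- array(0L, dim = c(PR, PC, years))
  ev_rows <- list(); px_rows_acc <- list(); eid <- 0L
  labels <- integer(grid$n_cells)

  # Chebyshev dilation of a logical mask by `m` pixels (separable).
  dilate <- function(mask, m) {
    if (m == 0L) return(mask)
    out <- mask
    for (s in seq_len(m)) {
      out[-1, ] <- out[-1, ] | mask[-nrow(mask), ]
      out[-nrow(out), ] <- out[-nrow(out), ] | mask[-1, ]
      mask <- out
    }
    for (s in seq_len(m)) {
      out[, -1] <- out[, -1] | mask[, -ncol(mask)]
      out[, -ncol(out)] <- out[, -ncol(out)] | mask[, -1]
      mask <- out
    }
    out
  }

  # extended-lattice linear index -> domain linear index (NA in the pad)
  ext_r <- (seq_len(PRe * PCe) - 1L) %% PRe + 1L - mg
  ext_c <- (seq_len(PRe * PCe) - 1L) %/% PRe + 1L - mg
  in_domain <- ext_r >= 1L & ext_r <= PR & ext_c >= 1L & ext_c <= PC
  dom_idx <- ifelse(in_domain, ext_r + (ext_c - 1L) * PR, NA_integer_)

  for (ri in seq_along(regions)) {
    sp <- regions[[ri]]
    labels[sp$cells] <- sp$region_id
    own_mask <- matrix(FALSE, PRe, PCe)   # region's domain pixels
    rc <- cell_rowcol(grid, sp$cells)
    for (k in seq_along(sp$cells)) {
      pr <- mg + (rc[k, 1] - 1L) * ppc + seq_len(ppc)
      pc <- mg + (rc[k, 2] - 1L) * ppc + seq_len(ppc)
      own_mask[pr, pc] <- TRUE
    }
    fuel_mask <- as.vector(dilate(own_mask, mg))  # ghost-padded fuel bed
    own <- as.vector(own_mask)
    fpx <- which(fuel_mask)
    area_scale <- length(fpx) / (length(sp$cells) * ppc^2)
    last_burn <- rep(0L, PRe * PCe)  # per-region fuel memory (year of burn)
    for (y in seq_len(years)) {
      n_ev <- rpois(1, sp$event_rate * length(sp$cells) * area_scale)
      if (n_ev == 0) next
      sizes_ha <- rlnorm(n_ev, sp$size_log_median, sp$size_log_sd)
      months <- draw_event_month(n_ev, sp$peak_month, sp$season_concentration)
      px_this_year <- list(); mo_this_year <- list(); nb <- 0L
      # admissible fuel this year: the region's padded bed, minus pixels
      # burned within the recovery window unless re-admitted with the
      # reburn propensity; fuel older than the window has fully recovered
      adm <- fuel_mask
      recent <- which(adm & last_burn > 0L & (y - last_burn) <= recovery_years)
      if (length(recent))
        adm[recent] <- runif(length(recent)) < sp$reburn_propensity
      for (e in seq_len(n_ev)) {
        size_px <- max(1L, as.integer(round(sizes_ha[e] / grid$pixel_area_ha)))
        free <- fpx[adm[fpx]]
        if (!length(free)) next
        seed_px <- if (length(free) == 1L) free else sample(free, 1L)
        blob <- grow_blob(seed_px, size_px, adm, PRe, PCe)
        if (!length(blob)) next
        m1 <- months[e]
        px_month <- rep(m1, length(blob))
        if (length(blob) > 1L && runif(1) < span_prob) {
          m2 <- (m1 %% 12L) + 1L
          n2 <- sample(seq_len(length(blob) - 1L), 1L)
          px_month[sample(length(blob), n2)] <- m2
        }
        adm[blob] <- FALSE
        last_burn[blob] <- y
        keep <- own[blob]
        if (!any(keep)) next  # burned wholly in the ghost pad
        dompx <- dom_idx[blob[keep]]
        eid <- eid + 1L
        ev_rows[[eid]] <- data.frame(
          event_id = eid, region_id = sp$region_id, year = year0 + y - 1L,
          month = m1, pixel_count = sum(keep),
          area_ha = sum(keep) * grid$pixel_area_ha,
          size_px_target = size_px)
        px_rows_acc[[eid]] <- data.frame(
          event_id = eid, pixel = dompx, year_idx = y,
          month = px_month[keep])
        nb <- nb + 1L
        px_this_year[[nb]] <- dompx
        mo_this_year[[nb]] <- px_month[keep]
      }
      if (nb) {
        slab <- cube[, , y]
        slab[unlist(px_this_year)] <- unlist(mo_this_year)
        cube[, , y] <- slab
      }
    }
  }
  truth <- structure(list(
    labels = labels,
    events = if (eid) do.call(rbind, ev_rows) else
      data.frame(event_id = integer(), region_id = integer(),
                 year = integer(), month = integer(),
                 pixel_count = integer(), area_ha = numeric(),
                 size_px_target = integer()),
    pixels = if (eid) do.call(rbind, px_rows_acc) else
      data.frame(event_id = integer(), pixel = integer(),
                 year_idx = integer(), month = integer()),
    climate_params = NULL, covariate_params = NULL),
    class = "synthetic_truth")
  structure(list(data = cube, grid = grid, year0 = as.integer(year0),
                 years = as.integer(years), truth = truth),
            class = "burned_cube")
}

#' @export
print.burned_cube <- function(x, ...) {
  cat(sprintf("burned_cube: %d x %d px, %d years from %d; %d burned pixel-years\n",
              dim(x$data)[1], dim(x$data)[2], x$years, x$year0,
              sum(x$data > 0)))
  invisible(x)
}

#' Simulate monthly climate series per grid cell
#'
#' Monthly 2 m temperature, precipitation and potential evapotranspiration
#' (PET) per cell. Temperature follows a north-south gradient (northern rows
#' hotter, emulating a tropics-ward increase) plus a mild seasonal cycle.
#' Precipitation is sinusoidal with its wet peak at `wet_peak_month` shifted
#' by each region's `dry_offset` (months), so dry-season timing differs
#' between regions; PET is near-constant with mild seasonality. Negative
#' draws of precipitation and PET are truncated at zero.
#'
#' With `flammability_strength > 0` a climatic flammability gradient is
#' planted on top: regions with higher planted event rates get hotter dry
#' seasons and a deeper precipitation trough (larger seasonal amplitude),
#' emulating the association between fire-conducive climate and fire
#' activity; `flammability_strength = 0` decouples climate from the
#' regimes apart from the dry-season phase.
#'
#' @param grid a `fire_grid`.
#' @param regions list of `region_spec` partitioning the grid.
#' @param years number of years.
#' @param seed RNG seed.
#' @param wet_peak_month calendar month of the precipitation maximum
#'   (default 1, i.e. an austral-summer wet season).
#' @param dry_offset numeric vector of per-region phase shifts in months
#'   (recycled; default shifts the 4th region by +2, giving it a later dry
#'   season).
#' @param precip_mean,precip_amp mean and relative amplitude of monthly
#'   precipitation (mm).
#' @param pet_mean,pet_amp mean and absolute amplitude of monthly PET (mm).
#' @param temp_south,temp_north mean annual temperature (degC) of the
#'   southernmost / northernmost row.
#' @param noise_sd relative noise sd applied to precipitation and PET and
#'   (in degC) to temperature.
#' @param flammability_strength coupling in `[0, 1]` between planted event
#'   rates and climatic flammability (dry-season temperature up, seasonal
#'   precipitation amplitude up).
#' @return `climate_series`: a data.frame with columns `cell_id`, `year`,
#'   `month`, `temp`, `precip`, `pet`, plus attribute `params` recording the
#'   per-region offsets.
#' @export
simulate_climate <- function(grid, regions, years, seed,
                             wet_peak_month = 1L,
                             dry_offset = c(0, 0, 0, 2),
                             precip_mean = 120, precip_amp = 0.85,
                             pet_mean = 100, pet_amp = 10,
                             temp_south = 22, temp_north = 25,
                             noise_sd = 0.05,
                             flammability_strength = 1) {
  stopifnot(inherits(grid, "fire_grid"), years >= 1,
            flammability_strength >= 0, flammability_strength <= 1)
  check_region_partition(grid, regions)
  set.seed(seed)
  dry_offset <- rep_len(dry_offset, length(regions))
  rates <- vapply(regions, `[[`, numeric(1), "event_rate")
  rs <- if (diff(range(rates)) > 0)
    (rates - min(rates)) / diff(range(rates)) else rep(0.5, length(rates))
  cell_off <- cell_hot <- cell_amp <- numeric(grid$n_cells)
  for (i in seq_along(regions)) {
    cell_off[regions[[i]]$cells] <- dry_offset[i]
    # flammability: hotter dry season, deeper precipitation trough
    cell_hot[regions[[i]]$cells] <- flammability_strength * (4.5 * rs[i] - 2.25)
    cell_amp[regions[[i]]$cells] <- precip_amp +
      flammability_strength * (0.12 * rs[i] - 0.06)
  }
  rc <- cell_rowcol(grid, seq_len(grid$n_cells))
  lat_frac <- if (grid$n_rows > 1) (rc[, 1] - 1) / (grid$n_rows - 1) else 0.5
  t_base <- temp_north + (temp_south - temp_north) * lat_frac

  n <- grid$n_cells * years * 12L
  df <- data.frame(
    cell_id = rep(seq_len(grid$n_cells), each = years * 12L),
    year = rep(rep(seq_len(years), each = 12L), times = grid$n_cells),
    month = rep(1:12, times = grid$n_cells * years))
  phase <- 2 * pi * (df$month - wet_peak_month - cell_off[df$cell_id]) / 12
  df$precip <- pmax(0, precip_mean *
                      (1 + cell_amp[df$cell_id] * cos(phase)) *
                      (1 + rnorm(n, 0, noise_sd)))
  # PET peaks half a year after the wet peak (dry season), mild amplitude
  df$pet <- pmax(0, pet_mean - pet_amp * cos(phase) +
                   pet_mean * rnorm(n, 0, noise_sd))
  # dry-season (anti-phase) warmth carries the planted flammability signal
  seas <- cos(2 * pi * (df$month - wet_peak_month - 6 - cell_off[df$cell_id]) / 12)
  df$temp <- t_base[df$cell_id] +
    (2 + cell_hot[df$cell_id]) * seas + 0.5 * cell_hot[df$cell_id] +
    rnorm(n, 0, noise_sd * 10)
  attr(df, "params") <- list(wet_peak_month = wet_peak_month,
                             dry_offset = dry_offset,
                             flammability = cell_hot)
  class(df) <- c("climate_series", "data.frame")
  df
}

#' Simulate per-cell anthropic covariates
#'
#' Percentage of anthropic area, its change within the period, population
#' density and livestock density, generated so that the anthropic level is
#' inversely ordered with the planted regional event rates (`strength = 1`;
#' `strength = 0` decouples covariates from the regimes entirely). A
#' `flammable_frac` column (share of the cell able to carry fire) decreases
#' with anthropic area.
#'
#' @param grid a `fire_grid`.
#' @param regions list of `region_spec` partitioning the grid.
#' @param seed RNG seed.
#' @param strength coupling in `[0, 1]` between event rate and covariates.
#' @return `anthropic_table`: data.frame with `cell_id`, `anthropic_pct`,
#'   `change_anthropic_pct`, `pop_density`, `livestock_density`,
#'   `flammable_frac`; attribute `params` holds the per-region means.
#' @export
simulate_anthropic <- function(grid, regions, seed, strength = 1) {
  stopifnot(strength >= 0, strength <= 1)
  check_region_partition(grid, regions)
  set.seed(seed)
  rates <- vapply(regions, `[[`, numeric(1), "event_rate")
  rs <- if (diff(range(rates)) > 0)
    (rates - min(rates)) / diff(range(rates)) else rep(0.5, length(rates))
  anth_mean <- 40 + strength * (30 - 60 * rs)   # low fire -> high anthropic
  cell_mean <- numeric(grid$n_cells)
  for (i in seq_along(regions)) cell_mean[regions[[i]]$cells] <- anth_mean[i]
  n <- grid$n_cells
  anth <- pmin(100, pmax(0, cell_mean + rnorm(n, 0, 6)))
  df <- data.frame(
    cell_id = seq_len(n),
    anthropic_pct = anth,
    change_anthropic_pct = rnorm(n, 1 + 0.05 * cell_mean, 2),
    pop_density = exp(rnorm(n, log(2 + 0.15 * cell_mean), 0.4)),
    livestock_density = exp(rnorm(n, log(5 + 0.30 * cell_mean), 0.4)),
    flammable_frac = pmin(1, pmax(0.2, 1 - 0.006 * anth + rnorm(n, 0, 0.02))))
  attr(df, "params") <- list(anth_mean = anth_mean, strength = strength)
  class(df) <- c("anthropic_table", "data.frame")
  df
}
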