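#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster interchange (NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE
#' header followed by rows north to south). Used for month-coded annual
#' burned-area layers and climate fields.
#'
#' @param m numeric/integer matrix, row 1 = northernmost.
#' @param path output file.
#' @param cellsize pixel size in the frame's units (metres).
#' @param xll,yll lower-left corner coordinates.
#' @param nodata NODATA value (default -9999).
#' @export
write_ascii_grid <- function(m, path, cellsize, xll = 0, yll = 0,
                             nodata = -9999) {
  m[is.na(m)] <- nodata
  hdr <- c(paste("NCOLS", ncol(m)), paste("NROWS", nrow(m)),
           paste("XLLCORNER", xll), paste("YLLCORNER", yll),
           paste("CELLSIZE", cellsize), paste("NODATA_VALUE", nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] or any conforming tool.
#' @return matrix with attributes `cellsize`, `xll`, `yll`; NODATA becomes
#'   `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  hdr <- setNames(as.numeric(kv[, 2]), toupper(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == hdr[["NROWS"]], ncol(m) == hdr[["NCOLS"]])
  if ("NODATA_VALUE" %in% names(hdr)) m[m == hdr[["NODATA_VALUE"]]] <- NA
  attr(m, "cellsize") <- hdr[["CELLSIZE"]]
  attr(m, "xll") <- hdr[["XLLCORNER"]]; attr(m, "yll") <- hdr[["YLLCORNER"]]
  m
}

#' Write a burned-area cube as annual month-coded ASCII grids
#'
#' One file per year, `burned_<year>.asc`, pixel values 0 (unburned) or the
#' burn month 1-12.
#'
#' @param cube a `burned_cube`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of paths.
#' @export
write_burned_cube <- function(cube, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(cube$years)
  for (y in seq_len(cube$years)) {
    paths[y] <- file.path(dir, sprintf("burned_%d.asc", cube$year0 + y - 1L))
    write_ascii_grid(cube$data[, , y], paths[y],
                     cellsize = cube$grid$pixel_size_m)
  }
  invisible(paths)
}

#' Construct a burned-area cube from a month-coded array
#'
#' Low-level constructor used by the readers and by tests; validates the
#' month-code dialect.
#'
#' @param data integer array `px_rows x px_cols x years` with values 0
#'   (unburned) or the burn month 1-12.
#' @param grid the `fire_grid` the array is laid on.
#' @param year0 first calendar year.
#' @return a `burned_cube` (without synthetic truth).
#' @export
burned_cube <- function(data, grid, year0 = 1985L) {
  if (length(dim(data)) == 2L) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L,
            dim(data)[1] == grid$px_rows, dim(data)[2] == grid$px_cols)
  if (any(data != round(data)) || any(data < 0) || any(data > 12))
    stop("month codes must be integers in 0..12")
  structure(list(data = array(as.integer(data), dim = dim(data)),
                 grid = grid, year0 = as.integer(year0),
                 years = dim(data)[3], truth = NULL),
            class = "burned_cube")
}

#' Read one annual month-coded burned-area layer
#'
#' Validates the month-code dialect (integer values 0-12; 0 = unburned,
#' 1-12 = mapping month) and consistency with a reference grid.
#'
#' @param path an ASCII-grid file.
#' @param grid the `fire_grid` the layer must conform to (dimensions and
#'   pixel size).
#' @return integer matrix of month codes.
#' @export
read_burned_year <- function(path, grid) {
  m <- read_ascii_grid(path)
  if (!isTRUE(all.equal(attr(m, "cellsize"), grid$pixel_size_m)))
    stop("pixel size mismatch with grid: ", path)
  if (nrow(m) != grid$px_rows || ncol(m) != grid$px_cols)
    stop("raster dimensions mismatch with grid: ", path)
  m[is.na(m)] <- 0
  if (any(m != round(m)) || any(m < 0) || any(m > 12))
    stop("not a month-coded burned-area layer (values must be integers 0-12): ",
         path)
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Read a burned-area cube from annual ASCII grids
#'
#' @param dir directory holding `burned_<year>.asc` files.
#' @param grid the `fire_grid`.
#' @return a `burned_cube` (without synthetic truth).
#' @export
read_burned_cube <- function(dir, grid) {
  files <- sort(list.files(dir, "^burned_\\d{4}\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no burned_<year>.asc files in ", dir)
  years <- as.integer(sub("^burned_(\\d{4})\\.asc$", "\\1", basename(files)))
  if (!all(diff(years) == 1L)) stop("annual layers are not consecutive")
  data <- array(0L, dim = c(grid$px_rows, grid$px_cols, length(files)))
  for (k in seq_along(files)) data[, , k] <- read_burned_year(files[k], grid)
  structure(list(data = data, grid = grid, year0 = years[1],
                 years = length(files), truth = NULL),
            class = "burned_cube")
}

#' Assemble a pipeline configuration
#'
#' @param n_rows,n_cols,pixels_per_cell,pixel_size_m grid parameters
#'   (defaults: the 10 x 10-cell, 50-pixel, 30 m synthetic test scale).
#' @param years_per_period period length in years (default 9).
#' @param n_periods number of consecutive periods simulated (default 1).
#' @param seed master RNG seed.
#' @param connectivity,buffer_m,min_area_ha event-delineation parameters.
#' @param k_range,var_threshold clustering parameters.
#' @param n_perm RDA permutations.
#' @param year0 first calendar year (default 1985).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_rows = 10, n_cols = 10, pixels_per_cell = 50,
                            pixel_size_m = 30, years_per_period = 9,
                            n_periods = 1, seed = 1, connectivity = 8,
                            buffer_m = 150, min_area_ha = 3,
                            k_range = 1:15, var_threshold = 0.95,
                            n_perm = 999, year0 = 1985L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full fire-regime characterization pipeline on synthetic data
#'
#' Simulates a burned-area cube, climate and anthropic covariates with the
#' default planted regions, then runs every downstream stage: event
#' delineation, regime metrics, climate summary, PCA + spatially
#' constrained clustering with BIC selection, random-forest / RDA /
#' gradient association, and (with `n_periods > 1`) cross-period projection
#' and trend fits. When `out_dir` is given, stage outputs are written as
#' CSV/ASCII-grid/JSON files together with a manifest (config echo, seed,
#' package version, file hashes) from which every output is re-derivable.
#'
#' @param config a `pipeline_config`.
#' @param out_dir optional output directory.
#' @param regions optional list of `region_spec`; defaults to
#'   [default_regions()] on the configured grid.
#' @return list with the stage objects: `grid`, `regions`, `cube`,
#'   `events`, `regimes` (per period), `climate`, `anthropic`, `clusters`,
#'   `assoc`, `trends` (non-NULL when `n_periods > 1`), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         regions = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  grid <- build_domain(config$n_rows, config$n_cols,
                       config$pixels_per_cell, config$pixel_size_m)
  if (is.null(regions)) regions <- default_regions(grid)
  years_total <- config$years_per_period * config$n_periods
  stage <- "simulate"
  res <- tryCatch({
    cube <- simulate_burned_cube(grid, regions, years_total, config$seed,
                                 year0 = config$year0)
    climate <- simulate_climate(grid, regions, years_total,
                                config$seed + 1L)
    anthro <- simulate_anthropic(grid, regions, config$seed + 2L)

    stage <- "events"
    events <- label_events(cube, config$connectivity, config$buffer_m,
                           config$min_area_ha)

    stage <- "metrics"
    flam <- anthro$flammable_frac * grid$cell_area_ha
    periods <- lapply(seq_len(config$n_periods), function(p)
      (p - 1L) * config$years_per_period + seq_len(config$years_per_period))
    regimes <- lapply(seq_along(periods), function(p)
      regime_table(cube, events, flam, periods[[p]],
                   config$min_area_ha, period_id = p))

    stage <- "climate"
    clim_sum <- climate_summary(climate)

    stage <- "cluster"
    clusters <- lapply(regimes, function(r)
      cluster_regions(r, grid, k_range = config$k_range,
                      var_threshold = config$var_threshold))

    stage <- "assoc"
    first <- clusters[[1]]
    Y <- transform_fire_variables(regimes[[1]])
    anth_pca <- fit_covariate_pca(anthro, "anthropic")
    clim_pca <- fit_covariate_pca(clim_sum, "climatic")
    assoc <- list(
      rf_anthropic = rf_accuracy(anthro[, ANTHROPIC_VARS], first$labels,
                                 seed = config$seed + 3L),
      rda_anthropic = rda_fire(Y, anthro[, ANTHROPIC_VARS],
                               config$n_perm, config$seed + 4L),
      rda_climatic = rda_fire(Y, clim_sum[, CLIMATIC_VARS],
                              config$n_perm, config$seed + 5L),
      anth_gradient = gradient_relation(first$pca$scores[, 1],
                                        anth_pca$scores[, 1]),
      clim_gradient = gradient_relation(first$pca$scores[, 1],
                                        clim_pca$scores[, 1]))

    stage <- "trends"
    trends <- NULL
    if (config$n_periods > 1) {
      annual <- regime_by_year(cube, events, flam, config$min_area_ha)
      pfreq <- do.call(rbind, lapply(seq_along(regimes), function(p)
        data.frame(cell_id = regimes[[p]]$cell_id, period_id = p,
                   frequency_q99 = regimes[[p]]$frequency_q99)))
      model1 <- clusters[[1]]$pca
      ppc1 <- do.call(rbind, lapply(seq_along(regimes), function(p)
        data.frame(cell_id = regimes[[p]]$cell_id, period_id = p,
                   pc1 = project_onto(model1, regimes[[p]])[, 1])))
      fits <- trend_maps(annual, pfreq, ppc1)
      last <- length(regimes)
      chg <- activity_change(
        project_onto(model1, regimes[[1]])[, 1],
        project_onto(model1, regimes[[last]])[, 1],
        clusters[[1]]$labels, clusters[[last]]$labels)
      trends <- list(fits = fits, change = chg)
    }
    list(grid = grid, regions = regions, cube = cube, events = events,
         regimes = regimes, climate = clim_sum, anthropic = anthro,
         clusters = clusters, assoc = assoc, trends = trends)
  }, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))

  if (!is.null(out_dir)) res$manifest <- write_pipeline_outputs(res, config,
                                                                out_dir)
  res
}

write_pipeline_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[length(paths) + 1]] <<- p
  }
  wr(res$events$events, "events.csv")
  for (p in seq_along(res$regimes))
    wr(as.data.frame(res$regimes[[p]]), sprintf("regimes_p%d.csv", p))
  wr(as.data.frame(res$climate), "climate_summary.csv")
  wr(as.data.frame(res$anthropic), "anthropic.csv")
  for (p in seq_along(res$clusters))
    wr(data.frame(cell_id = seq_len(res$grid$n_cells),
                  region = res$clusters[[p]]$labels),
       sprintf("labels_p%d.csv", p))
  if (!is.null(res$trends)) {
    wr(as.data.frame(res$trends$fits), "trend_fits.csv")
    wr(as.data.frame(attr(res$trends$fits, "summary")), "trend_summary.csv")
  }
  manifest <- list(
    package = "pyroregions",
    version = as.character(utils::packageVersion("pyroregions")),
    r_version = R.version.string,
    config = unclass(config),
    outputs = data.frame(file = basename(unlist(paths)),
                         md5 = unname(tools::md5sum(unlist(paths)))))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  manifest
}
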