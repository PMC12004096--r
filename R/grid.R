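#' Define a rectangular analysis grid
#'
#' Builds the square-cell grid that all fire-regime statistics are computed
#' on. The grid lives in a Cartesian equal-area frame (metres), origin at the
#' upper-left corner, rows increasing southwards. Every cell is a square of
#' `pixels_per_cell` x `pixels_per_cell` raster pixels; cell ids are row-major
#' (cell 1 is the north-west corner). The real-data analogue is a 30 km grid
#' of 1000 x 1000 Landsat pixels of 30 m; tests use much smaller grids.
#'
#' @param n_rows,n_cols number of cell rows / columns (positive integers).
#' @param pixels_per_cell pixels along one side of a cell.
#' @param pixel_size_m pixel side length in metres.
#' @return an object of class `fire_grid`: a list with the arguments plus
#'   `cell_size_m`, `n_cells`, `px_rows`, `px_cols`, `pixel_area_ha` and
#'   `cell_area_ha`.
#' @examples
#' g <- build_domain(10, 10, 50, 30)   # 1.5 km cells, 500 x 500 px
#' g$cell_area_ha                      # 225 ha
#' @export
build_domain <- function(n_rows, n_cols, pixels_per_cell, pixel_size_m) {
  stop_if_not_positive(n_rows, "n_rows")
  stop_if_not_positive(n_cols, "n_cols")
  stop_if_not_positive(pixels_per_cell, "pixels_per_cell")
  stop_if_not_positive(pixel_size_m, "pixel_size_m")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  pixels_per_cell <- as.integer(pixels_per_cell)
  g <- list(
    n_rows = n_rows, n_cols = n_cols,
    pixels_per_cell = pixels_per_cell,
    pixel_size_m = pixel_size_m,
    cell_size_m = pixels_per_cell * pixel_size_m,
    n_cells = n_rows * n_cols,
    px_rows = n_rows * pixels_per_cell,
    px_cols = n_cols * pixels_per_cell,
    pixel_area_ha = pixel_size_m^2 / 1e4,
    cell_area_ha = (pixels_per_cell * pixel_size_m)^2 / 1e4
  )
  class(g) <- "fire_grid"
  g
}

#' @export
print.fire_grid <- function(x, ...) {
  cat(sprintf(
    "fire_grid: %d x %d cells (%.3g km side, %.4g ha), %d x %d pixels of %g m\n",
    x$n_rows, x$n_cols, x$cell_size_m / 1000, x$cell_area_ha,
    x$px_rows, x$px_cols, x$pixel_size_m))
  invisible(x)
}

#' Map pixel coordinates to cell ids
#'
#' @param grid a `fire_grid`.
#' @param px_row,px_col 1-based pixel indices (row from north, col from west).
#' @return integer row-major cell ids.
#' @export
cell_of_pixel <- function(grid, px_row, px_col) {
  cr <- (px_row - 1L) %/% grid$pixels_per_cell
  cc <- (px_col - 1L) %/% grid$pixels_per_cell
  as.integer(cr * grid$n_cols + cc + 1L)
}

#' Row/column position of cells
#' @param grid a `fire_grid`.
#' @param cell_id integer cell ids (row-major).
#' @return two-column matrix (`row`, `col`), 1-based.
#' @export
cell_rowcol <- function(grid, cell_id) {
  r <- (cell_id - 1L) %/% grid$n_cols + 1L
  c <- (cell_id - 1L) %% grid$n_cols + 1L
  cbind(row = r, col = c)
}

#' Contiguity graph over grid cells
#'
#' Queen contiguity (8 neighbours for interior cells, diagonals included) is
#' the default adjacency for both the spatially constrained clustering and
#' the no-fire seasonality imputation; rook (4 neighbours) is available.
#'
#' @param grid a `fire_grid`.
#' @param type `"queen"` (default) or `"rook"`.
#' @return object of class `contiguity_graph`: list with `n` (cells) and
#'   `edges`, a two-column integer matrix of unordered adjacent cell pairs
#'   (first column < second column).
#' @export
build_contiguity <- function(grid, type = c("queen", "rook")) {
  type <- match.arg(type)
  R <- grid$n_rows; C <- grid$n_cols
  ids <- seq_len(R * C)
  rc <- cell_rowcol(grid, ids)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (type == "queen") offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- do.call(rbind, lapply(offs, function(o) {
    r2 <- rc[, 1] + o[1]; c2 <- rc[, 2] + o[2]
    ok <- r2 >= 1 & r2 <= R & c2 >= 1 & c2 <= C
    cbind(ids[ok], (r2[ok] - 1L) * C + c2[ok])
  }))
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(list(n = R * C, edges = edges, type = type),
            class = "contiguity_graph")
}

#' Neighbouring cells of one cell
#'
#' Neighbours at Chebyshev distance exactly `ring` (ring 1 = the immediate
#' 8-neighbourhood under queen contiguity).
#'
#' @param grid a `fire_grid`.
#' @param cell_id a single cell id.
#' @param ring ring radius (default 1).
#' @return integer vector of cell ids (may be empty at the domain edge).
#' @export
cell_neighbors <- function(grid, cell_id, ring = 1L) {
  rc <- cell_rowcol(grid, cell_id)
  d <- seq(-ring, ring)
  rr <- rep(rc[1] + d, times = 2 * ring + 1)
  cc <- rep(rc[2] + d, each = 2 * ring + 1)
  keep <- pmax(abs(rr - rc[1]), abs(cc - rc[2])) == ring &
    rr >= 1 & rr <= grid$n_rows & cc >= 1 & cc <= grid$n_cols
  as.integer((rr[keep] - 1L) * grid$n_cols + cc[keep])
}

#' Exact area-weighted zonal mean of a raster over grid cells
#'
#' Averages a georeferenced field over each grid cell, weighting every raster
#' pixel by the exact area of its intersection with the cell (pixels
#' straddling a cell boundary contribute fractionally). Both the raster and
#' the grid are axis-aligned rectangles in the same Cartesian frame, so
#' intersection areas are closed-form. Cells with zero raster overlap get
#' `NA`.
#'
#' @param field numeric matrix; `field[i, j]` is the pixel in raster row `i`
#'   (from north) and column `j` (from west).
#' @param origin_xy numeric length-2: x (east) and y (north) of the raster's
#'   upper-left corner, metres. Grid origin is (0, 0) upper-left.
#' @param pixel_size_m raster pixel side, metres (need not match the grid's).
#' @param grid a `fire_grid`.
#' @return numeric vector of per-cell means, indexed by cell id.
#' @export
zonal_mean <- function(field, origin_xy, pixel_size_m, grid) {
  stopifnot(is.matrix(field), length(origin_xy) == 2, pixel_size_m > 0)
  nr <- nrow(field); nc <- ncol(field)
  # pixel j spans x: origin + (j-1)*s .. origin + j*s ; row i spans y: origin - i*s .. origin - (i-1)*s
  px_x0 <- origin_xy[1] + (seq_len(nc) - 1) * pixel_size_m
  px_x1 <- px_x0 + pixel_size_m
  px_y1 <- origin_xy[2] - (seq_len(nr) - 1) * pixel_size_m  # top
  px_y0 <- px_y1 - pixel_size_m                             # bottom
  s <- grid$cell_size_m
  out <- rep(NA_real_, grid$n_cells)
  for (cell in seq_len(grid$n_cells)) {
    rc <- cell_rowcol(grid, cell)
    cx0 <- (rc[2] - 1) * s; cx1 <- rc[2] * s
    cy1 <- -(rc[1] - 1) * s; cy0 <- -rc[1] * s  # y decreases southwards
    jx <- which(px_x1 > cx0 & px_x0 < cx1)
    iy <- which(px_y1 > cy0 & px_y0 < cy1)
    if (!length(jx) || !length(iy)) next
    wx <- pmin(px_x1[jx], cx1) - pmax(px_x0[jx], cx0)
    wy <- pmin(px_y1[iy], cy1) - pmax(px_y0[iy], cy0)
    w <- outer(wy, wx)
    v <- field[iy, jx, drop = FALSE]
    out[cell] <- sum(w * v) / sum(w)
  }
  out
}
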