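# Fixture builders and independent brute-force oracles shared by the tests.

# A cube built directly from a month-coded array (row, col, year).
make_cube <- function(data, pixel_size_m = 30, pixels_per_cell = 1L,
                      year0 = 1985L) {
  if (length(dim(data)) == 2L) data <- array(data, dim = c(dim(data), 1L))
  g <- build_domain(dim(data)[1] / pixels_per_cell,
                    dim(data)[2] / pixels_per_cell,
                    pixels_per_cell, pixel_size_m)
  burned_cube(data, g, year0)
}

# Random sparse month-coded cube: a few rectangular patches plus salt noise.
random_cube <- function(nr, nc, years, n_patches = 6, noise_px = 15,
                        pixel_size_m = 30) {
  a <- array(0L, dim = c(nr, nc, years))
  for (p in seq_len(n_patches)) {
    h <- sample(1:6, 1); w <- sample(1:6, 1)
    r0 <- sample(1:(nr - h + 1), 1); c0 <- sample(1:(nc - w + 1), 1)
    y <- sample(years, 1); m <- sample(1:12, 1)
    a[r0:(r0 + h - 1), c0:(c0 + w - 1), y] <- m
  }
  for (p in seq_len(noise_px)) {
    a[sample(nr, 1), sample(nc, 1), sample(years, 1)] <- sample(1:12, 1)
  }
  make_cube(a, pixel_size_m)
}

# Brute-force event delineation oracle: explicit O(n^2) pairwise relation,
# naive union-find, and component-level distance merging iterated to a
# fixed point. Returns the partition of burned records as an integer vector
# aligned with pyroregions' pixel record order (px_row, px_col, year_idx).
oracle_label_partition <- function(cube, connectivity, buffer_m,
                                   buffer_ignores_time = FALSE) {
  w <- which(cube$data > 0L, arr.ind = TRUE)
  o <- order(w[, 3], w[, 2], w[, 1])
  w <- w[o, , drop = FALSE]
  n <- nrow(w)
  if (n == 0L) return(integer(0))
  t <- 12 * (w[, 3] - 1) +
    vapply(seq_len(n), function(i) cube$data[w[i, 1], w[i, 2], w[i, 3]],
           numeric(1)) - 1
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    dr <- abs(w[i, 1] - w[j, 1]); dc <- abs(w[i, 2] - w[j, 2])
    adjacent <- if (connectivity == 8) max(dr, dc) <= 1 else dr + dc <= 1
    if (adjacent && abs(t[i] - t[j]) <= 1) union_(i, j)
  }
  if (buffer_m > 0) {
    px <- cube$grid$pixel_size_m
    repeat {
      comp <- vapply(seq_len(n), find, integer(1))
      ids <- unique(comp)
      merged <- FALSE
      if (length(ids) >= 2) {
        for (a in seq_along(ids)) for (b in seq_len(a - 1)) {
          ia <- which(comp == ids[a]); ib <- which(comp == ids[b])
          if (!buffer_ignores_time) {
            gap <- max(min(t[ib]) - max(t[ia]), min(t[ia]) - max(t[ib]))
            if (gap > 1) next
          }
          dmin <- Inf
          for (i in ia) for (j in ib) {
            dr <- max(abs(w[i, 1] - w[j, 1]) - 1, 0)
            dc <- max(abs(w[i, 2] - w[j, 2]) - 1, 0)
            dmin <- min(dmin, sqrt(dr^2 + dc^2) * px)
          }
          if (dmin <= buffer_m) { union_(ia[1], ib[1]); merged <- TRUE }
        }
      }
      if (!merged) break
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

# Partition of pyroregions::label_events pixels (pre-filter components),
# aligned with the oracle's record order.
package_label_partition <- function(cube, connectivity, buffer_m,
                                    buffer_ignores_time = FALSE) {
  ev <- label_events(cube, connectivity = connectivity, buffer_m = buffer_m,
                     min_area_ha = 0, buffer_ignores_time = buffer_ignores_time)
  px <- ev$pixels
  o <- order(px$year_idx, px$px_col, px$px_row)
  match(px$event_id[o], unique(px$event_id[o]))
}

# Two partitions are equal iff their co-membership structure is identical.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    isTRUE(all.equal(adjusted_rand_index(a, b), 1))
}

# Canonical member-set sequence of a merge history (for comparison with
# stats::hclust on complete graphs).
merge_member_sets <- function(merge) {
  sets <- list()
  out <- vector("list", nrow(merge))
  for (s in seq_len(nrow(merge))) {
    members <- function(x) if (x < 0) -x else sets[[x]]
    sets[[s]] <- sort(c(members(merge[s, 1]), members(merge[s, 2])))
    out[[s]] <- sets[[s]]
  }
  out
}

# Small planted-regime landscape on a coarse grid for faster module tests.
# Mirrors the default four-regime taxonomy but with rates and sizes scaled
# to the smaller cells (36 ha at ppc = 20) so fuel beds do not saturate.
small_landscape <- function(seed, years = 9, n = 6, ppc = 20) {
  g <- build_domain(n, n, ppc, 30)
  rc <- cell_rowcol(g, seq_len(g$n_cells))
  top <- rc[, 1] <= ceiling(n / 2)
  left <- rc[, 2] <= ceiling(n / 2)
  q <- list(which(!top & !left), which(!top & left),
            which(top & left), which(top & !left))
  rates <- c(1.2, 0.7, 0.45, 1.1)
  sizes <- c(6, 5, 4, 4.5)
  reburn <- c(0.55, 0.5, 0.3, 0.7)
  concs <- c(2.5, 2.5, 5, 8)
  peaks <- c(8L, 8L, 8L, 10L)
  regs <- lapply(1:4, function(i)
    region_spec(i, q[[i]], rates[i], log(sizes[i]), 0.25, peaks[i],
                concs[i], reburn[i]))
  names(regs) <- c("high", "intermediate", "low", "late_season")
  cube <- simulate_burned_cube(g, regs, years, seed = seed)
  list(grid = g, regions = regs, cube = cube)
}
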