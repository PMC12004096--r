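#' Delineate fire events from a month-coded burned-area cube
#'
#' Merges burned pixels into fire events (fire polygons) under the
#' spatio-temporal rule: two burned pixel records belong to the same event
#' iff they are connected under the transitive closure of
#' (a) raster adjacency (4- or 8-connectivity, or the same pixel location in
#' different years) with a month gap of at most 1 on the continuous month
#' index `t = 12 * (year - year0) + month - 1` (so December to January merges
#' across calendar years); and
#' (b) component-level proximity: two components whose pixel-dissolved
#' borders lie within `buffer_m` of each other and whose month spans overlap
#' or are consecutive (gap <= 1 on `t`) are merged, iterated to a fixed
#' point. Finally events smaller than `min_area_ha` are discarded (the area
#' filter is applied after all merging).
#'
#' Border-to-border distance is the exact Euclidean distance between closed
#' pixel squares (edge-sharing pixels are at distance 0).
#'
#' @param cube a `burned_cube` (see [simulate_burned_cube()] or
#'   [read_burned_cube()]).
#' @param connectivity 8 (default; diagonals touch) or 4.
#' @param buffer_m border-to-border merge distance in metres (default 150).
#' @param min_area_ha minimum event area in hectares (default 3); events with
#'   `area_ha < min_area_ha` are dropped.
#' @param buffer_ignores_time if `TRUE`, the buffer merge (b) ignores the
#'   temporal-compatibility requirement (distance only).
#' @return object of class `fire_events`: list with
#'   `events` (data.frame: `event_id`, `t_start`, `t_end`, `pixel_count`,
#'   `area_ha`) and `pixels` (data.frame of burned pixel records:
#'   `px_row`, `px_col`, `year_idx`, `month`, `t`, `event_id`; records of
#'   filtered-out events carry `event_id = NA`), plus `grid`, `year0` and the
#'   call parameters.
#' @export
label_events <- function(cube, connectivity = 8, buffer_m = 150,
                         min_area_ha = 3, buffer_ignores_time = FALSE) {
  stopifnot(inherits(cube, "burned_cube"))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (buffer_m < 0) stop("buffer_m must be >= 0")
  if (min_area_ha < 0) stop("min_area_ha must be >= 0")
  if (is.null(cube$grid) || is.null(cube$grid$pixel_size_m))
    stop("cube has no georeferencing (grid with pixel size)")

  rec <- burn_records(cube)
  if (nrow(rec) == 0L)
    return(structure(list(events = data.frame(event_id = integer(),
                                              t_start = integer(),
                                              t_end = integer(),
                                              pixel_count = integer(),
                                              area_ha = numeric()),
                          pixels = rec, grid = cube$grid, year0 = cube$year0,
                          connectivity = connectivity, buffer_m = buffer_m,
                          min_area_ha = min_area_ha),
                     class = "fire_events"))

  comp <- adjacency_components(rec, cube$grid, connectivity)
  comp <- buffer_merge(rec, comp, cube$grid, buffer_m, buffer_ignores_time)

  px_area <- cube$grid$pixel_area_ha
  dt <- data.table::data.table(comp = comp, t = rec$t)
  ev <- dt[, list(t_start = min(t), t_end = max(t),
                  pixel_count = .N), by = "comp"]
  ev[, "area_ha" := ev$pixel_count * px_area]
  data.table::setorderv(ev, c("t_start", "comp"))
  keep <- ev$area_ha >= min_area_ha
  ev$event_id <- NA_integer_
  ev$event_id[keep] <- seq_len(sum(keep))
  id_of <- ev$event_id[match(comp, ev$comp)]
  rec$event_id <- id_of
  events <- as.data.frame(ev[keep, c("event_id", "t_start", "t_end",
                                     "pixel_count", "area_ha")])
  structure(list(events = events, pixels = rec, grid = cube$grid,
                 year0 = cube$year0, connectivity = connectivity,
                 buffer_m = buffer_m, min_area_ha = min_area_ha),
            class = "fire_events")
}

#' @export
print.fire_events <- function(x, ...) {
  cat(sprintf(
    "fire_events: %d events (>= %g ha) from %d burned pixel records; buffer %g m, %d-connectivity\n",
    nrow(x$events), x$min_area_ha, nrow(x$pixels), x$buffer_m,
    x$connectivity))
  invisible(x)
}

# Burned pixel records of a cube: one row per (pixel, year) with month > 0.
burn_records <- function(cube) {
  w <- which(cube$data > 0L, arr.ind = TRUE)
  if (nrow(w) == 0L)
    return(data.frame(px_row = integer(), px_col = integer(),
                      year_idx = integer(), month = integer(),
                      t = integer(), event_id = integer()))
  month <- cube$data[w]
  data.frame(px_row = w[, 1], px_col = w[, 2], year_idx = w[, 3],
             month = as.integer(month),
             t = 12L * (w[, 3] - 1L) + as.integer(month) - 1L,
             event_id = NA_integer_)
}

# Stage (a): connected components of burned records under raster adjacency
# (chosen connectivity, plus same-location across years) with |dt| <= 1.
adjacency_components <- function(rec, grid, connectivity) {
  n <- nrow(rec)
  dt <- data.table::data.table(id = seq_len(n), r = rec$px_row,
                               c = rec$px_col, t = rec$t)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  pairs <- vector("list", length(offs))
  shifted <- data.table::copy(dt)
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    shifted[, c("r2", "c2") := list(dt$r + o[1], dt$c + o[2])]
    m <- merge(dt, shifted[, c("id", "r2", "c2", "t")],
               by.x = c("r", "c"), by.y = c("r2", "c2"),
               allow.cartesian = TRUE, suffixes = c("", ".nb"))
    m <- m[abs(m$t - m$t.nb) <= 1L & m$id != m$id.nb]
    pairs[[k]] <- cbind(m$id, m$id.nb)
  }
  edges <- do.call(rbind, pairs)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

# Stage (b): merge components within buffer_m (border to border) whose month
# spans have gap <= 1 (unless ignore_time); iterated to a fixed point.
#
# Because the border distance between merged groups is the minimum over
# their member components, the <= buffer relation between groups is exactly
# "some member pair is within buffer". So the proximity edges between the
# stage-(a) components are computed once, at pixel level:
#  - touching/overlapping pairs (distance 0) from a +/-1-offset location
#    join over all records;
#  - pairs with a gap of one pixel or more from a block join over boundary
#    pixels only (the minimum distance between non-touching pixel sets is
#    attained at boundary pixels).
# The time-compatibility fixpoint then runs on that small component graph.
buffer_merge <- function(rec, comp, grid, buffer_m, ignore_time = FALSE) {
  if (buffer_m <= 0) return(comp)
  px <- grid$pixel_size_m
  buf_px <- buffer_m / px
  n <- nrow(rec)
  dt <- data.table::data.table(r = rec$px_row, c = rec$px_col,
                               comp = comp, id = seq_len(n))

  K <- max(comp) + 1
  pair_code <- function(a, b) pmin(a, b) * K + pmax(a, b)  # unordered pair
  codes <- list()

  # distance-0 edges: records at the same or an 8-adjacent pixel location
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    sh <- dt[, list(r2 = r + o[1], c2 = c + o[2], comp2 = comp)]
    m <- merge(dt[, list(r, c, comp)], sh, by.x = c("r", "c"),
               by.y = c("r2", "c2"), allow.cartesian = TRUE)
    m <- m[m$comp != m$comp2]
    codes[[length(codes) + 1L]] <- unique(pair_code(m$comp, m$comp2))
  }

  if (buf_px >= 1) {
    # boundary pixels: at least one rook neighbour missing from the component
    loc <- unique(dt[, c("r", "c", "comp")])
    loc[, "idx" := seq_len(nrow(loc))]
    has_nb <- rep(0L, nrow(loc))
    for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      sh <- loc[, list(r2 = r + o[1], c2 = c + o[2], comp)]
      found <- merge(loc, sh, by.x = c("r", "c", "comp"),
                     by.y = c("r2", "c2", "comp"))
      has_nb[found$idx] <- has_nb[found$idx] + 1L
    }
    bnd <- loc[has_nb < 4L]
    # block join: any pair within gap <= buf_px shares a block neighbourhood
    bs <- as.integer(ceiling(buf_px)) + 1L
    bnd[, c("br", "bc") := list(r %/% bs, c %/% bs)]
    for (dr in -1:1) for (dc in -1:1) {
      sh <- bnd[, list(br2 = br + dr, bc2 = bc + dc, r2 = r, c2 = c,
                       comp2 = comp)]
      m <- merge(bnd[, list(br, bc, r, c, comp)], sh,
                 by.x = c("br", "bc"), by.y = c("br2", "bc2"),
                 allow.cartesian = TRUE)
      m <- m[m$comp != m$comp2]
      if (nrow(m)) {
        gr <- pmax(abs(m$r - m$r2) - 1L, 0L)
        gc <- pmax(abs(m$c - m$c2) - 1L, 0L)
        m <- m[gr * gr + gc * gc <= buf_px^2]
      }
      codes[[length(codes) + 1L]] <- unique(pair_code(m$comp, m$comp2))
    }
  }
  codes <- unique(unlist(codes))
  if (!length(codes)) return(comp)
  edges <- cbind(codes %/% K, codes %% K)

  # fixpoint: union edge-connected groups whose month spans have gap <= 1
  ids <- sort(unique(comp))
  cid <- match(comp, ids)
  agg <- data.table::data.table(t = rec$t, cid = cid)[
    , list(t0 = min(t), t1 = max(t)), keyby = "cid"]
  t0 <- agg$t0; t1 <- agg$t1
  ea <- match(edges[, 1], ids); eb <- match(edges[, 2], ids)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  repeat {
    changed <- FALSE
    for (p in seq_along(ea)) {
      ra <- find(ea[p]); rb <- find(eb[p])
      if (ra == rb) next
      if (!ignore_time &&
          max(t0[rb] - t1[ra], t0[ra] - t1[rb]) > 1) next
      root <- min(ra, rb); other <- max(ra, rb)
      parent[other] <- root
      t0[root] <- min(t0[ra], t0[rb]); t1[root] <- max(t1[ra], t1[rb])
      changed <- TRUE
    }
    if (!changed) break
  }
  root <- vapply(seq_along(ids), find, integer(1))
  ids[root[cid]]
}

#' Summarize a fire-event size distribution
#'
#' Diagnostic for the expected heavy-tailed distribution of event sizes:
#' smoothed-ECDF quantiles plus a Hill tail-index estimate over the largest
#' tenth of events.
#'
#' @param events a `fire_events` object or a numeric vector of sizes (ha).
#' @param probs quantile levels.
#' @return list with `n`, `quantiles`, `log_median`, `hill_tail_index`
#'   (`NA` when fewer than 20 events) and `empty` flag.
#' @export
event_sizes_check <- function(events,
                              probs = c(0.05, 0.25, 0.5, 0.75, 0.95, 0.99)) {
  sizes <- if (inherits(events, "fire_events")) events$events$area_ha
           else as.numeric(events)
  if (!length(sizes))
    return(list(n = 0L, quantiles = setNames(rep(NA_real_, length(probs)),
                                             paste0("q", probs * 100)),
                log_median = NA_real_, hill_tail_index = NA_real_,
                empty = TRUE))
  qs <- vapply(probs, function(p) secdf_quantile(sizes, p), numeric(1))
  names(qs) <- paste0("q", probs * 100)
  hill <- NA_real_
  if (length(sizes) >= 20) {
    srt <- sort(sizes, decreasing = TRUE)
    k <- max(2L, floor(length(sizes) * 0.1))
    hill <- 1 / mean(log(srt[seq_len(k)] / srt[k + 1L]))
  }
  list(n = length(sizes), quantiles = qs,
       log_median = log(secdf_quantile(sizes, 0.5)),
       hill_tail_index = hill, empty = FALSE)
}
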