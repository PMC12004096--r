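test_that("degenerate cubes are handled", {
  cube <- make_cube(array(0L, dim = c(10, 10, 2)))
  ev <- label_events(cube)
  expect_equal(nrow(ev$events), 0L)

  expect_error(label_events(cube, connectivity = 6), "connectivity")
  expect_error(label_events(cube, buffer_m = -5), "buffer_m")
})

test_that("the 3 ha area filter drops small events after merging", {
  # a 2 x 2 patch of 30 m pixels is 0.36 ha: always filtered
  a <- array(0L, dim = c(10, 10, 1))
  a[3:4, 3:4, 1] <- 5L
  ev <- label_events(make_cube(a))
  expect_equal(nrow(ev$events), 0L)
  # but survives with the filter off
  ev0 <- label_events(make_cube(a), min_area_ha = 0)
  expect_equal(ev0$events$pixel_count, 4L)
  expect_equal(ev0$events$area_ha, 0.36)
})

test_that("consecutive-month adjacent patches merge into one event", {
  # two 40-pixel blobs sharing an edge, months t and t+1 -> one event
  a <- array(0L, dim = c(20, 20, 1))
  a[1:8, 1:5, 1] <- 3L    # 40 px in March
  a[9:16, 1:5, 1] <- 4L   # 40 px in April, edge-adjacent
  ev <- label_events(make_cube(a), buffer_m = 0)
  expect_equal(nrow(ev$events), 1L)
  expect_equal(ev$events$pixel_count, 80L)
  expect_equal(ev$events$area_ha, 7.2)
  expect_equal(ev$events$t_start, 2)   # March of year 1 on the 0-based index
  expect_equal(ev$events$t_end, 3)

  # two months apart -> two events
  a[9:16, 1:5, 1] <- 5L
  ev2 <- label_events(make_cube(a), buffer_m = 0, min_area_ha = 0)
  expect_equal(nrow(ev2$events), 2L)

  # December to January across a year boundary merges on the month index
  b <- array(0L, dim = c(20, 20, 2))
  b[1:8, 1:5, 1] <- 12L
  b[9:16, 1:5, 2] <- 1L
  ev3 <- label_events(make_cube(b), buffer_m = 0)
  expect_equal(nrow(ev3$events), 1L)
  expect_equal(ev3$events$t_end - ev3$events$t_start, 1)
})

test_that("the border-to-border buffer merges nearby same-season patches", {
  # 30 m pixels: a 4-column gap is 120 m (merge at 150 m),
  # a 7-column gap is 210 m (no merge)
  a <- array(0L, dim = c(12, 30, 1))
  a[1:6, 1:10, 1] <- 6L
  a[1:6, 15:24, 1] <- 6L   # gap columns 11:14 -> 120 m
  ev <- label_events(make_cube(a), buffer_m = 150)
  expect_equal(nrow(ev$events), 1L)

  b <- array(0L, dim = c(12, 40, 1))
  b[1:6, 1:10, 1] <- 6L
  b[1:6, 18:27, 1] <- 6L   # gap columns 11:17 -> 210 m
  ev2 <- label_events(make_cube(b), buffer_m = 150)
  expect_equal(nrow(ev2$events), 2L)
  # and with a temporally incompatible pair the merge is blocked even at
  # 120 m, unless the buffer is told to ignore time
  d <- array(0L, dim = c(12, 30, 1))
  d[1:6, 1:10, 1] <- 3L
  d[1:6, 15:24, 1] <- 8L
  expect_equal(nrow(label_events(make_cube(d), buffer_m = 150)$events), 2L)
  expect_equal(nrow(label_events(make_cube(d), buffer_m = 150,
                                 buffer_ignores_time = TRUE)$events), 1L)
})

test_that("label_events matches the brute-force oracle on random cubes", {
  set.seed(101)
  for (rep in 1:8) {
    cube <- random_cube(24, 24, 3)
    for (conn in c(4, 8)) for (buf in c(0, 150)) {
      expect_true(same_partition(
        package_label_partition(cube, conn, buf),
        oracle_label_partition(cube, conn, buf)),
        label = sprintf("rep %d conn %d buffer %g", rep, conn, buf))
    }
  }
})

test_that("pre-filter events partition the burned pixels", {
  ls <- small_landscape(seed = 5, years = 3)
  ev <- label_events(ls$cube, min_area_ha = 0)
  expect_equal(sum(ev$events$pixel_count), sum(ls$cube$data > 0))
  expect_false(anyNA(ev$pixels$event_id))
})

test_that("more buffer or a stricter filter never increases event count", {
  ls <- small_landscape(seed = 6, years = 3)
  n_by_buffer <- vapply(c(0, 60, 150, 300), function(b)
    nrow(label_events(ls$cube, buffer_m = b, min_area_ha = 0)$events),
    numeric(1))
  expect_true(all(diff(n_by_buffer) <= 0))
  n_by_area <- vapply(c(0, 1, 3, 10), function(ma)
    nrow(label_events(ls$cube, min_area_ha = ma)$events), numeric(1))
  expect_true(all(diff(n_by_area) <= 0))
})

test_that("event size summaries recover planted distributions", {
  s <- event_sizes_check(rep(4, 10))
  expect_equal(unname(s$quantiles["q50"]), 4)
  expect_equal(unname(s$quantiles["q99"]), 4)

  s1 <- event_sizes_check(12.5)
  expect_equal(unname(s1$quantiles["q50"]), 12.5)

  expect_true(event_sizes_check(numeric(0))$empty)

  set.seed(9)
  sizes <- rlnorm(600, log(8), 0.6)
  s2 <- event_sizes_check(sizes)
  expect_lt(abs(s2$log_median - log(8)) / log(8), 0.1)
  expect_false(is.na(s2$hill_tail_index))
})
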