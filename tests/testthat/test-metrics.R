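test_that("sECDF quantiles match an independent interpolated-ECDF oracle", {
  expect_equal(secdf_quantile(c(5, 5, 5), 0.3), 5)
  expect_equal(secdf_quantile(c(5, 5, 5), 0.99), 5)
  expect_error(secdf_quantile(numeric(0), 0.5), "empty")
  expect_error(secdf_quantile(1:5, 1), "in \\(0, 1\\)")

  # all-distinct samples sit at the (i - 0.5)/n plotting positions, which
  # is quantile type 5; stats::quantile is the independent oracle
  x <- c(3.2, 0.5, 7.1, 2.2, 9.4, 4.4, 6.0)
  for (q in c(0.1, 0.25, 0.5, 0.9)) {
    expect_equal(secdf_quantile(x, q),
                 unname(quantile(x, q, type = 5)))
  }
  expect_equal(secdf_quantile(1:100, 0.5), 50.5)

  # never exceeds the sample range
  expect_lte(secdf_quantile(x, 0.999), max(x))
  expect_gte(secdf_quantile(x, 0.001), min(x))

  # tied integer data: CDF interpolates between distinct values; oracle by
  # hand for counts 95 x 0, 4 x 1, 1 x 2: F(1) = 0.97, F(2) = 0.995
  cnt <- c(rep(0, 95), rep(1, 4), 2)
  expect_equal(secdf_quantile(cnt, 0.99), 1 + (0.99 - 0.97) / 0.025)

  # unsmoothed variant returns an order statistic
  expect_equal(secdf_quantile(x, 0.5, smoothing = "none"), sort(x)[4])
})

test_that("the fire-year is anchored at the modal burning month", {
  v <- numeric(12); v[8] <- 10
  expect_equal(fire_year_offset(v), 8L)
  # ties take the earliest month
  v2 <- numeric(12); v2[7] <- 5; v2[9] <- 5
  expect_equal(fire_year_offset(v2), 7L)
  expect_true(is.na(fire_year_offset(numeric(12))))
})

test_that("season peak is the burned-area-weighted sECDF median, circular", {
  one <- numeric(12); one[9] <- 42
  expect_equal(season_peak(one), 9)

  # uniform burning over months m..m+3 -> midpoint m + 1.5
  u <- numeric(12); u[5:8] <- 1
  expect_equal(season_peak(u), 6.5)

  # shifting all burning by +2 months shifts the result by exactly +2
  base <- numeric(12); base[6:9] <- c(1, 3, 2, 1)
  shifted <- numeric(12); shifted[8:11] <- c(1, 3, 2, 1)
  expect_equal(circular_month_diff(season_peak(shifted), season_peak(base)), 2)

  # rotation across the calendar wrap stays circularly consistent
  wrap <- numeric(12); wrap[c(11, 12, 1, 2)] <- c(1, 3, 2, 1)
  expect_equal(circular_month_diff(season_peak(wrap), season_peak(base)), 5)

  expect_true(is.na(season_peak(numeric(12))))
})

test_that("compute_regime reproduces hand-computed values", {
  g <- build_domain(1, 1, 10, 30)  # one 300 m cell: 9 ha
  a <- array(0L, dim = c(10, 10, 9))
  a[1:5, 1:5, 2] <- 7L             # a single 25-pixel July burn (2.25 ha)
  cube <- burned_cube(a, g)
  ctx <- cell_period_context(cube, 1L, flammable_area_ha = 900)
  reg <- compute_regime(ctx, event_areas_ha = 10)
  expect_equal(reg$n_fires, 1 / 900 * 1e4)
  expect_equal(reg$size_q50_ha, 10)
  expect_equal(reg$size_q99_ha, 10)
  expect_equal(reg$burned_area_norm, 25 * 0.09 / 900)
  expect_equal(reg$season_peak_month, 7)
  expect_false(reg$imputed)

  # every pixel burned in every one of the 9 years -> frequency 9
  full <- burned_cube(array(8L, dim = c(10, 10, 9)), g)
  ctxf <- cell_period_context(full, 1L)
  regf <- compute_regime(ctxf, event_areas_ha = rep(5, 3))
  expect_equal(regf$frequency_q99, 9)

  # no events routes to imputation
  empty <- compute_regime(cell_period_context(cube, 1L), numeric(0))
  expect_true(is.na(empty$imputed))

  # burning with zero flammable area is inconsistent
  expect_error(compute_regime(cell_period_context(cube, 1L,
                                                  flammable_area_ha = 0),
                              event_areas_ha = 1),
               "flammable")
})

test_that("no-fire imputation uses the minimum fire size and neighbours", {
  g <- build_domain(3, 3, 10, 30)
  season <- rep(NA_real_, 9)
  season[c(1, 2, 3, 4, 6, 7, 8, 9)] <- 8  # all neighbours peak in August
  imp <- impute_no_fire(g, 5L, season, flammable_area_ha = 900)
  expect_equal(imp$size_q50_ha, 3)
  expect_equal(imp$size_q99_ha, 3)
  expect_equal(imp$frequency_q99, 1)
  expect_equal(imp$n_fires, 1 / 900 * 1e4)
  expect_equal(imp$burned_area_norm, 3 / 900)
  expect_equal(imp$season_peak_month, 8)
  expect_true(imp$imputed)

  # December and February neighbours average to January, not July
  season2 <- rep(NA_real_, 9)
  season2[2] <- 12; season2[8] <- 2
  imp2 <- impute_no_fire(g, 5L, season2, 900)
  expect_equal(imp2$season_peak_month, 1)

  # an empty 8-neighbourhood expands to the next ring
  g5 <- build_domain(5, 5, 10, 30)
  season3 <- rep(NA_real_, 25)
  season3[1] <- 6  # only a ring-2 neighbour of the centre has a season
  expect_message(imp3 <- impute_no_fire(g5, 13L, season3, 900), "ring")
  expect_equal(imp3$season_peak_month, 6)
})

test_that("per-cell burned areas reproduce the per-cell cube totals", {
  ls <- small_landscape(seed = 7, years = 3)
  ev <- label_events(ls$cube)
  reg <- regime_table(ls$cube, ev)
  # true burned pixel-years per cell, straight from the cube
  w <- which(ls$cube$data > 0, arr.ind = TRUE)
  cells <- cell_of_pixel(ls$grid, w[, 1], w[, 2])
  truth <- numeric(ls$grid$n_cells)
  tab <- table(cells)
  truth[as.integer(names(tab))] <- as.integer(tab) * ls$grid$pixel_area_ha
  keep <- !reg$imputed
  expect_equal(reg$burned_area_norm[keep] * ls$grid$cell_area_ha,
               truth[reg$cell_id[keep]])
  # and summed over non-imputed cells they match the cube total there
  expect_equal(sum(reg$burned_area_norm[keep]) * ls$grid$cell_area_ha,
               sum(truth[reg$cell_id[keep]]))
})

test_that("regimes recover the planted regional structure", {
  seasons <- matrix(NA_real_, 3, 4)
  nf_ok <- logical(3)
  for (s in 1:3) {
    ls <- small_landscape(seed = s + 20)
    ev <- label_events(ls$cube)
    reg <- regime_table(ls$cube, ev)
    lab <- ls$cube$truth$labels
    for (r in 1:4)
      seasons[s, r] <- circular_mean_month(reg$season_peak_month[lab == r])
    rates <- vapply(ls$regions, `[[`, numeric(1), "event_rate")
    nf <- tapply(reg$n_fires, lab, mean)
    nf_ok[s] <- identical(order(nf), order(rates))
  }
  planted <- vapply(small_landscape(1)$regions, `[[`, numeric(1),
                    "peak_month")
  for (r in 1:4)
    expect_lt(max(abs(circular_month_diff(seasons[, r], planted[r]))), 0.5)
  expect_true(all(nf_ok))
})

test_that("season statistics are invariant under calendar rotation", {
  # rotating the month labels of the cube rotates the season peak exactly
  a <- array(0L, dim = c(10, 10, 2))
  set.seed(31)
  burn <- matrix(runif(100) < 0.3, 10, 10)
  a[, , 1][burn] <- sample(5:9, sum(burn), replace = TRUE)
  g <- build_domain(1, 1, 10, 30)
  ctx <- cell_period_context(burned_cube(a, g), 1L)
  base <- season_peak(rowSums(ctx$monthly_burned))
  rot <- a
  rot[, , 1][burn] <- ((a[, , 1][burn] + 3 - 1) %% 12) + 1
  ctx2 <- cell_period_context(burned_cube(rot, g), 1L)
  expect_equal(circular_month_diff(
    season_peak(rowSums(ctx2$monthly_burned)), base), 3)
})
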