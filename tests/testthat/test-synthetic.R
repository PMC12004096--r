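test_that("region specifications are validated", {
  g <- build_domain(4, 4, 5, 30)
  expect_error(region_spec(1, 1:4, -1, log(5), 0.3, 8), "event_rate")
  expect_error(region_spec(1, 1:4, 1, log(5), 0.3, 13))
  # disconnected cell set rejected when a grid is supplied
  expect_error(region_spec(1, c(1, 16), 1, log(5), 0.3, 8, grid = g),
               "not connected")
  # connected diagonal pair accepted under queen contiguity
  expect_s3_class(region_spec(1, c(1, 6), 1, log(5), 0.3, 8, grid = g),
                  "region_spec")

  regs <- list(region_spec(1, 1:8, 1, log(5), 0.3, 8),
               region_spec(2, 9:15, 1, log(5), 0.3, 8))
  expect_error(simulate_burned_cube(g, regs, 1, seed = 1), "cover")
  regs2 <- list(region_spec(1, 1:9, 1, log(5), 0.3, 8),
                region_spec(2, 9:16, 1, log(5), 0.3, 8))
  expect_error(simulate_burned_cube(g, regs2, 1, seed = 1), "overlap")
})

test_that("identical seeds give bit-identical cubes and tables", {
  g <- build_domain(4, 4, 10, 30)
  regs <- list(region_spec(1, 1:8, 1.5, log(2), 0.3, 7),
               region_spec(2, 9:16, 0.5, log(2), 0.3, 9))
  c1 <- simulate_burned_cube(g, regs, 3, seed = 42)
  c2 <- simulate_burned_cube(g, regs, 3, seed = 42)
  expect_identical(c1$data, c2$data)
  expect_identical(c1$truth$events, c2$truth$events)
  c3 <- simulate_burned_cube(g, regs, 3, seed = 43)
  expect_false(identical(c1$data, c3$data))

  a1 <- simulate_anthropic(g, regs, seed = 7)
  a2 <- simulate_anthropic(g, regs, seed = 7)
  expect_identical(a1, a2)
  s1 <- simulate_climate(g, regs, 2, seed = 7)
  s2 <- simulate_climate(g, regs, 2, seed = 7)
  expect_identical(s1, s2)
})

test_that("zero event rate yields an empty cube and truth", {
  g <- build_domain(3, 3, 8, 30)
  regs <- list(region_spec(1, 1:9, 0, log(5), 0.3, 8))
  cube <- simulate_burned_cube(g, regs, 4, seed = 1)
  expect_true(all(cube$data == 0L))
  expect_equal(nrow(cube$truth$events), 0L)
})

test_that("planted event counts follow the Poisson contract", {
  # one region, rate 2, 25 cells, 9 years -> mean 450 planted events;
  # margin 0 so the seeded count is exactly Poisson(450)
  g <- build_domain(5, 5, 10, 30)
  regs <- list(region_spec(1, 1:25, 2, log(0.5), 0.3, 8))
  totals <- vapply(1:20, function(s) {
    cube <- simulate_burned_cube(g, regs, 9, seed = s, margin_px = 0)
    nrow(cube$truth$events)
  }, numeric(1))
  expect_lt(abs(mean(totals) - 450), 3 * sqrt(450 / 20))
})

test_that("every burned pixel belongs to exactly one planted event", {
  ls <- small_landscape(seed = 3, years = 3)
  px <- ls$cube$truth$pixels
  expect_equal(nrow(px), sum(ls$cube$data > 0))
  expect_equal(anyDuplicated(px[, c("pixel", "year_idx")]), 0L)
  # pixel records reproduce the cube's month codes
  i <- sample(nrow(px), 50)
  arr_idx <- cbind((px$pixel[i] - 1) %% ls$grid$px_rows + 1,
                   (px$pixel[i] - 1) %/% ls$grid$px_rows + 1,
                   px$year_idx[i])
  expect_equal(ls$cube$data[arr_idx], px$month[i])
})

test_that("planted months are circularly concentrated at the peak", {
  g <- build_domain(5, 5, 10, 30)
  regs <- list(region_spec(1, 1:25, 2, log(0.5), 0.3, 10,
                           season_concentration = 8))
  months <- unlist(lapply(1:20, function(s) {
    simulate_burned_cube(g, regs, 3, seed = s)$truth$events$month
  }))
  expect_lt(abs(circular_month_diff(circular_mean_month(months), 10)), 1)
  # monthly totals peak (mode) at the planted peak month
  expect_equal(as.integer(names(which.max(table(months)))), 10L)
})

test_that("anthropic covariates track planted activity inversely", {
  g <- build_domain(6, 6, 5, 30)
  regs <- list(region_spec(1, 1:12, 3, log(5), 0.3, 8),
               region_spec(2, 13:24, 1, log(5), 0.3, 8),
               region_spec(3, 25:36, 0.2, log(5), 0.3, 8))
  at <- simulate_anthropic(g, regs, seed = 1)
  expect_true(all(at$anthropic_pct >= 0 & at$anthropic_pct <= 100))
  expect_true(all(at$pop_density >= 0))
  lab <- integer(36)
  for (r in regs) lab[r$cells] <- r$region_id
  m <- tapply(at$anthropic_pct, lab, mean)
  # anthropic level ordered inversely to event rate
  expect_true(m[1] < m[2] && m[2] < m[3])

  # strength 0 decouples: region means statistically indistinguishable
  at0 <- simulate_anthropic(g, regs, seed = 1, strength = 0)
  m0 <- tapply(at0$anthropic_pct, lab, mean)
  expect_lt(diff(range(m0)), 10)
})

test_that("synthetic climate plants dry-season timing and flammability", {
  g <- build_domain(4, 4, 5, 30)
  regs <- list(region_spec(1, 1:8, 2, log(5), 0.3, 8),
               region_spec(2, 9:16, 2, log(5), 0.3, 8))

  # no noise, same phase: one dry-season peak everywhere
  s0 <- simulate_climate(g, regs, 3, seed = 1, dry_offset = c(0, 0),
                         noise_sd = 0, flammability_strength = 0)
  cs0 <- climate_summary(s0)
  expect_equal(length(unique(cs0$peak_dry_season)), 1L)

  # two regions with a 2-month phase offset differ by 2 months in peak
  s2 <- simulate_climate(g, regs, 3, seed = 1, dry_offset = c(0, 2),
                         noise_sd = 0, flammability_strength = 0)
  cs2 <- climate_summary(s2)
  p1 <- unique(cs2$peak_dry_season[1:8])
  p2 <- unique(cs2$peak_dry_season[9:16])
  expect_equal(circular_month_diff(p2, p1), 2)

  # wet variant: precipitation above PET every month -> no dry season
  sw <- simulate_climate(g, regs, 2, seed = 1, precip_mean = 500,
                         precip_amp = 0.1, pet_mean = 100, noise_sd = 0)
  csw <- climate_summary(sw)
  expect_true(all(csw$n_dry_months == 0))
})
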