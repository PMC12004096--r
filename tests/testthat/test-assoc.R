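test_that("random forests separate separable classes and report sane CIs", {
  set.seed(61)
  n <- 120
  lab <- rep(1:3, each = n / 3)
  X <- data.frame(a = lab * 2 + rnorm(n, 0, 0.2),
                  b = -lab + rnorm(n, 0, 0.2))
  r <- rf_accuracy(X, lab, n_trees = 300, seed = 1)
  expect_gte(r$accuracy, 0.95)
  # point estimate inside its own CI
  expect_true(r$ci[1] <= r$accuracy && r$accuracy <= r$ci[2])
  expect_named(r$importance, c("a", "b"))

  expect_error(rf_accuracy(X, rep(1, n)), "two classes")
  expect_error(rf_accuracy(X[1:10, ], rep(1:2, 5)), "n >= 30")
})

test_that("null-covariate forests have chance-level accuracy", {
  covered <- 0
  for (s in 1:5) {
    set.seed(s + 70)
    lab <- rep(1:2, each = 40)
    X <- data.frame(a = rnorm(80), b = rnorm(80))
    r <- rf_accuracy(X, lab, n_trees = 300, seed = s)
    covered <- covered + (r$ci[1] <= 0.5 && 0.5 <= r$ci[2])
  }
  expect_gte(covered, 4)
})

test_that("covariate PCAs transform densities and anchor orientation", {
  g <- build_domain(6, 6, 5, 30)
  regs <- list(region_spec(1, 1:18, 3, log(5), 0.3, 8),
               region_spec(2, 19:36, 0.3, log(5), 0.3, 8))
  at <- simulate_anthropic(g, regs, seed = 2)
  m <- fit_covariate_pca(at, "anthropic")
  expect_setequal(m$variable_names,
                  c("anthropic_pct", "change_anthropic_pct",
                    "pop_density", "livestock_density"))
  expect_gt(m$loadings["anthropic_pct", "PC1"], 0)
  # the single planted latent gradient dominates PC1
  expect_gt(m$variance_fraction[1], 0.5)
  # cells with more anthropic area score higher on PC1
  expect_gt(cor(m$scores[, 1], at$anthropic_pct), 0)

  expect_error(fit_covariate_pca(at[, 1:2, drop = FALSE], "anthropic"),
               "missing covariate")

  cs <- climate_summary(simulate_climate(g, regs, 3, seed = 3,
                                         dry_offset = c(0, 2)))
  mc <- fit_covariate_pca(cs, "climatic")
  expect_gt(mc$loadings["t_dry", "PC1"], 0)
})

test_that("RDA matches a brute-force per-response regression oracle", {
  set.seed(81)
  Y <- matrix(rnorm(24), 8, 3)
  X <- matrix(rnorm(16), 8, 2)
  r <- rda_fire(Y, X, n_perm = 49, seed = 1)
  # oracle: sum over responses of regression SS over total centred SS
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  ss_fit <- sum(vapply(1:3, function(j)
    sum(fitted(lm(Yc[, j] ~ Xc - 1))^2), numeric(1)))
  r2_oracle <- ss_fit / sum(Yc^2)
  expect_equal(r$r2, r2_oracle, tolerance = 1e-10)
  expect_equal(r$r2_adj, 1 - (1 - r2_oracle) * 7 / 5, tolerance = 1e-10)
  expect_true(r$permutation_p > 0)

  # exact linear response: R2 = 1
  B <- matrix(rnorm(6), 2, 3)
  Yx <- X %*% B
  rx <- rda_fire(Yx, X, n_perm = 19, seed = 1)
  expect_equal(rx$r2, 1)
  expect_equal(rx$r2_adj, 1)

  # aliased predictors are dropped, not fatal
  X3 <- cbind(X, alias = X[, 1] * 2)
  expect_message(r3 <- rda_fire(Y, X3, n_perm = 19, seed = 1), "aliased")
  expect_equal(r3$r2, r$r2, tolerance = 1e-10)

  # R2 never decreases when a predictor is added
  X4 <- cbind(X, extra = rnorm(8))
  r4 <- rda_fire(Y, X4, n_perm = 19, seed = 1)
  expect_gte(r4$r2, r$r2 - 1e-12)
})

test_that("RDA agrees with vegan and behaves under the null", {
  skip_if_not_installed("vegan")
  set.seed(82)
  Y <- matrix(rnorm(150), 50, 3)
  X <- data.frame(u = rnorm(50), v = rnorm(50))
  ours <- rda_fire(Y, X, n_perm = 99, seed = 2)
  ref <- vegan::rda(Y ~ u + v, data = X)
  expect_equal(ours$r2, unname(vegan::RsquareAdj(ref)$r.squared),
               tolerance = 1e-10)
  expect_equal(ours$r2_adj, unname(vegan::RsquareAdj(ref)$adj.r.squared),
               tolerance = 1e-10)

  # independent predictors at n = 500: adjusted R2 near zero
  set.seed(83)
  Y0 <- matrix(rnorm(1500), 500, 3)
  X0 <- matrix(rnorm(1000), 500, 2)
  r0 <- rda_fire(Y0, X0, n_perm = 99, seed = 3)
  expect_lt(abs(r0$r2_adj), 0.05)
})

test_that("gradient relations report signed correlations with CIs", {
  set.seed(91)
  act <- rnorm(60)
  anth <- -0.8 * act + rnorm(60, 0, 0.4)
  g <- gradient_relation(act, anth)
  expect_equal(g$sign, "negative")
  expect_lt(g$pearson_ci[2], 0)
  expect_lt(g$spearman, 0)

  clim <- 0.8 * act + rnorm(60, 0, 0.4)
  expect_equal(gradient_relation(act, clim)$sign, "positive")

  # permuted cells: CI covers zero (checked over a few permutations)
  cover <- vapply(1:5, function(i) {
    set.seed(i)
    gr <- gradient_relation(act, sample(anth))
    gr$pearson_ci[1] <= 0 && 0 <= gr$pearson_ci[2]
  }, logical(1))
  expect_gte(sum(cover), 4)

  expect_error(gradient_relation(1:2, 1:2), "n >= 3")
})
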