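test_that("constrained Ward equals stats::hclust Ward on complete graphs", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(15:40, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    ours <- constrained_ward(X, graph = NULL)
    ref <- hclust(dist(X)^2, method = "ward.D")
    expect_equal(merge_member_sets(ours$merge), merge_member_sets(ref$merge))
    expect_equal(ours$height, ref$height, tolerance = 1e-10)
  }
})

test_that("only contiguous clusters may merge", {
  # chain a-b-c-d where the ends are mutually nearest: a,d cannot merge first
  X <- matrix(c(0, 10, 20, 0.5), ncol = 1)
  graph <- structure(list(n = 4L,
                          edges = cbind(1:3, 2:4), type = "chain"),
                     class = "contiguity_graph")
  hc <- constrained_ward(X, graph)
  first <- sort(abs(hc$merge[1, ]))
  expect_false(identical(first, c(1L, 4L)))

  # disconnected graph: components never merge
  g2 <- structure(list(n = 4L, edges = cbind(c(1, 3), c(2, 4)),
                       type = "split"), class = "contiguity_graph")
  X2 <- matrix(c(0, 0.1, 0.05, 0.12), ncol = 1)  # all features similar
  hc2 <- constrained_ward(X2, g2)
  expect_equal(hc2$k_min, 2L)
  lab <- cut_ward(hc2, 2)
  expect_equal(lab[1], lab[2])
  expect_equal(lab[3], lab[4])
  expect_false(lab[1] == lab[3])
})

test_that("every dendrogram cut yields connected clusters", {
  set.seed(22)
  g <- build_domain(6, 6, 1, 30)
  graph <- build_contiguity(g)
  X <- matrix(rnorm(36 * 2), 36, 2)
  hc <- constrained_ward(X, graph)
  ig <- igraph::graph_from_edgelist(apply(graph$edges, 2, as.character),
                                    directed = FALSE)
  for (k in c(2, 5, 9, 14)) {
    lab <- cut_ward(hc, k)
    expect_equal(length(unique(lab)), k)
    for (cl in unique(lab)) {
      sub <- igraph::induced_subgraph(ig, as.character(which(lab == cl)))
      expect_equal(igraph::count_components(sub), 1L)
    }
  }
})

test_that("BIC selects planted cluster counts and k = 1 uses the total SS", {
  g <- build_domain(10, 10, 1, 30)
  graph <- build_contiguity(g)
  rc <- cell_rowcol(g, 1:100)
  planted <- 1 + (rc[, 1] > 5) * 2 + (rc[, 2] > 5)
  hits <- 0
  for (s in 1:5) {
    set.seed(s + 400)
    mu <- matrix(rnorm(12, sd = 4), 4, 3)
    X <- mu[planted, ] + matrix(rnorm(300), 100, 3)
    hc <- constrained_ward(X, graph)
    sol <- select_k(hc, X, 1:15)
    expect_equal(sol$scores$W[sol$scores$k == 1],
                 sum(scale(X, scale = FALSE)^2))
    hits <- hits + (sol$k == 4 &&
                      adjusted_rand_index(sol$labels, planted) == 1)
  }
  expect_gte(hits, 4)
})

test_that("the Dunn index rewards separation", {
  X <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 10, 0.1), 20, 2))
  good <- rep(1:2, each = 20)
  bad <- rep(1:2, times = 20)
  expect_gt(dunn_index(X, good), dunn_index(X, bad))
  expect_true(is.na(dunn_index(X, rep(1, 40))))
})

test_that("the hard-partition BIC variant is monotone-prone, as documented", {
  # the plug-in form keeps decreasing on pure noise, which is why the
  # mixture form is the default
  set.seed(30)
  g <- build_domain(6, 6, 1, 30)
  X <- matrix(rnorm(72), 36, 2)
  hc <- constrained_ward(X, build_contiguity(g))
  hard <- select_k(hc, X, 1:12, bic = "hard")
  mix <- select_k(hc, X, 1:12, bic = "mixture")
  expect_gte(hard$k, mix$k)
})

test_that("the full regionalization path recovers planted regimes", {
  ls <- small_landscape(seed = 41, n = 10, ppc = 20)
  ev <- label_events(ls$cube)
  reg <- regime_table(ls$cube, ev)
  sol <- cluster_regions(reg, ls$grid)
  expect_gte(adjusted_rand_index(cut_ward(sol$merge_history, 4),
                                 ls$cube$truth$labels), 0.7)
  expect_equal(ncol(sol$retained_scores), sol$pca$n_retained)

  # without seasonality the feature matrix has five columns
  X5 <- transform_fire_variables(reg, drop_season = TRUE)
  expect_equal(ncol(X5), 5L)
  sol5 <- cluster_regions(reg, ls$grid, drop_season = TRUE)
  expect_true(sol5$k >= 2)
})

test_that("seasonality-only contrasts vanish without the season variable", {
  # two regions identical in activity, differing only in season peak
  g <- build_domain(6, 6, 15, 30)
  regs <- list(region_spec(1L, 1:18, 1.2, log(4.5), 0.25, 7,
                           season_concentration = 15),
               region_spec(2L, 19:36, 1.2, log(4.5), 0.25, 11,
                           season_concentration = 15))
  cube <- simulate_burned_cube(g, regs, 9, seed = 51)
  truth <- cube$truth$labels
  reg <- regime_table(cube, label_events(cube))
  with_season <- cluster_regions(reg, g, k_range = 1:6)
  without <- cluster_regions(reg, g, k_range = 1:6, drop_season = TRUE)
  # never more structure without the season than with it
  expect_lte(without$k, with_season$k)
  # the two-region cut recovers the planted split only when the season
  # variable is present
  ari_with <- adjusted_rand_index(
    cut_ward(with_season$merge_history, 2), truth)
  ari_without <- adjusted_rand_index(
    cut_ward(without$merge_history, 2), truth)
  expect_gte(ari_with, 0.9)
  expect_lt(ari_without, 0.5)
})
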