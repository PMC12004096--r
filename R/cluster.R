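#' Agglomerative Ward clustering under a spatial contiguity constraint
#'
#' Hierarchical minimum-variance (Ward) clustering in which only clusters
#' adjacent in a contiguity graph may merge, so every cluster at every cut
#' is a spatially connected region; geographically disconnected areas with
#' similar features end up in different clusters by construction.
#' Dissimilarities start as squared Euclidean distances between rows of `X`
#' and are updated with the Ward Lance-Williams recurrence; on a merge the
#' two adjacency lists are unioned. Ties are broken by the smallest pair of
#' cluster ids, clusters being identified by their smallest member node.
#' On a complete graph the merge sequence is identical to unconstrained
#' Ward clustering. If the graph is disconnected, merging proceeds per
#' component and stops when only components remain.
#'
#' @param X numeric matrix of features (rows = graph nodes, e.g. retained
#'   PCA scores).
#' @param graph a `contiguity_graph` ([build_contiguity()]), or `NULL` for a
#'   complete graph (unconstrained Ward).
#' @return object of class `constr_ward`: `merge` (hclust-style matrix:
#'   negative = singleton node, positive = earlier merge row), `height`
#'   (Ward cost, squared-distance scale), `n`, `k_min` (clusters remaining
#'   when no allowed merge is left; 1 when the graph is connected).
#' @export
constrained_ward <- function(X, graph = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 1)
  if (!is.null(graph)) stopifnot(inherits(graph, "contiguity_graph"),
                                 graph$n == n)
  D <- as.matrix(dist(X))^2
  A <- matrix(is.null(graph), n, n)
  if (!is.null(graph) && nrow(graph$edges)) {
    A[graph$edges] <- TRUE
    A[graph$edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  diag(A) <- FALSE
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  # row i of D/A currently represents the cluster whose smallest member is
  # min_member[i]; merge_row[i] is its row in the merge matrix (0 = leaf)
  min_member <- seq_len(n)
  merge_row <- integer(n)
  merge <- matrix(0L, max(n - 1L, 0L), 2L)
  height <- numeric(max(n - 1L, 0L))
  step <- 0L
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    Dv <- D[idx, idx, drop = FALSE]
    Av <- A[idx, idx, drop = FALSE]
    Dv[!Av] <- Inf
    Dv[lower.tri(Dv, diag = TRUE)] <- Inf
    if (!any(is.finite(Dv))) break  # disconnected graph: components remain
    dmin <- min(Dv)
    cand <- which(Dv == dmin, arr.ind = TRUE)
    if (nrow(cand) > 1L) {  # smallest (id, id) pair among ties
      ids <- cbind(min_member[idx[cand[, 1]]], min_member[idx[cand[, 2]]])
      ids <- cbind(pmin(ids[, 1], ids[, 2]), pmax(ids[, 1], ids[, 2]))
      cand <- cand[order(ids[, 1], ids[, 2])[1], , drop = FALSE]
    }
    i <- idx[cand[1, 1]]; j <- idx[cand[1, 2]]
    if (min_member[j] < min_member[i]) { tmp <- i; i <- j; j <- tmp }
    step <- step + 1L
    merge[step, ] <- c(
      if (merge_row[i] == 0L) -min_member[i] else merge_row[i],
      if (merge_row[j] == 0L) -min_member[j] else merge_row[j])
    height[step] <- dmin
    # Ward Lance-Williams update of D[., i <- i+j] over active k != i, j
    ks <- idx[idx != i & idx != j]
    if (length(ks)) {
      ni <- size[i]; nj <- size[j]; nk <- size[ks]
      dnew <- ((ni + nk) * D[ks, i] + (nj + nk) * D[ks, j] - nk * dmin) /
        (ni + nj + nk)
      D[ks, i] <- dnew; D[i, ks] <- dnew
      A[ks, i] <- A[i, ks] <- A[ks, i] | A[ks, j]
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    merge_row[i] <- step
    min_member[i] <- min(min_member[i], min_member[j])
  }
  structure(list(merge = merge[seq_len(step), , drop = FALSE],
                 height = height[seq_len(step)],
                 n = n, k_min = n - step),
            class = "constr_ward")
}

#' @export
print.constr_ward <- function(x, ...) {
  cat(sprintf("constr_ward: %d nodes, %d merges (k_min = %d)\n",
              x$n, nrow(x$merge), x$k_min))
  invisible(x)
}

#' Cut a constrained-Ward dendrogram into k clusters
#'
#' Replays the first `n - k` merges (the dendrogram cut); labels are
#' renumbered 1..k in order of each cluster's smallest member node.
#'
#' @param hc a `constr_ward`.
#' @param k number of clusters, between `hc$k_min` and `hc$n`.
#' @return integer label vector over nodes.
#' @export
cut_ward <- function(hc, k) {
  stopifnot(inherits(hc, "constr_ward"), k >= hc$k_min, k <= hc$n)
  lab <- seq_len(hc$n)
  cluster_of_merge <- integer(nrow(hc$merge))
  n_steps <- hc$n - k
  for (s in seq_len(n_steps)) {
    a <- hc$merge[s, 1]; b <- hc$merge[s, 2]
    ca <- if (a < 0) lab[-a] else cluster_of_merge[a]
    cb <- if (b < 0) lab[-b] else cluster_of_merge[b]
    keep <- min(ca, cb)
    lab[lab == ca | lab == cb] <- keep
    cluster_of_merge[s] <- keep
  }
  match(lab, sort(unique(lab)))
}

# Total within-cluster sum of squares of X under a labeling.
within_ss <- function(X, labels) {
  X <- as.matrix(X)
  sum(vapply(split(seq_len(nrow(X)), labels), function(ix) {
    xc <- X[ix, , drop = FALSE]
    sum(scale(xc, center = TRUE, scale = FALSE)^2)
  }, numeric(1)))
}

#' Dunn index of a partition
#'
#' Ratio of the minimum between-cluster (single-linkage) distance to the
#' maximum within-cluster diameter, on Euclidean distances; larger is
#' better-separated. `Inf` when every cluster is a singleton, `NA` for a
#' single cluster.
#'
#' @param X feature matrix.
#' @param labels cluster labels.
#' @return Dunn index.
#' @export
dunn_index <- function(X, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  D <- as.matrix(dist(X))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  diam <- suppressWarnings(max(D[same & !is.na(same)], na.rm = TRUE))
  sep <- min(D[!same & !is.na(same)])
  if (!is.finite(diam) || diam == 0) return(Inf)
  sep / diam
}

# BIC of the spherical Gaussian mixture induced by a hard partition:
# means = cluster means, shared variance = W/(nd), mixing = cluster shares;
# the log-likelihood is the full mixture likelihood over all points.
bic_spherical_mixture <- function(X, labels) {
  n <- nrow(X); d <- ncol(X)
  groups <- split(seq_len(n), labels)
  k <- length(groups)
  mu <- do.call(rbind, lapply(groups, function(ix)
    colMeans(X[ix, , drop = FALSE])))
  W <- within_ss(X, labels)
  s2 <- max(W / (n * d), .Machine$double.eps)
  lpi <- log(vapply(groups, length, 0) / n)
  # n x k matrix of log component densities
  sq <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(mu) +
    outer(rep(1, n), rowSums(mu^2))
  lc <- sweep(-sq / (2 * s2), 2, lpi - d / 2 * log(2 * pi * s2), "+")
  mx <- apply(lc, 1, max)
  ll <- sum(mx + log(rowSums(exp(lc - mx))))
  list(bic = -2 * ll + log(n) * (k * d + k), W = W)
}

#' Choose the number of fire-regime regions by BIC
#'
#' For each candidate `k` the dendrogram is cut and scored under a
#' spherical Gaussian model; the Dunn index and the mean silhouette width
#' are computed on the same feature space for consultation. The returned
#' solution minimizes BIC.
#'
#' Two BIC variants are available. The default, `"mixture"`, evaluates the
#' full spherical Gaussian mixture likelihood of the cut-induced model
#' (cluster means, shared variance `W/(nd)`, mixing proportions), with
#' `ln(n) (kd + k)` penalty: splitting a genuinely Gaussian cluster into
#' two half-clusters leaves the mixture likelihood almost unchanged, so the
#' criterion has an interior minimum at real structure. The `"hard"`
#' variant is the plug-in form `n d ln(W/(nd)) + ln(n) k d` on the hard
#' assignment; because Ward-optimized cuts reduce `W` by a roughly
#' scale-free fraction per split, that form decreases almost monotonically
#' in `k` at moderate `n` and is provided for comparison only.
#'
#' @param hc a `constr_ward`.
#' @param X the feature matrix the clustering was run on (retained scores).
#' @param k_range candidate cluster counts (default 1:15, clipped to the
#'   feasible range).
#' @param bic `"mixture"` (default) or `"hard"`.
#' @return object of class `cluster_solution`: `k`, `labels`, `scores`
#'   (data.frame with `k`, `bic`, `dunn`, `silhouette`, `W`),
#'   `merge_history`.
#' @export
select_k <- function(hc, X, k_range = 1:15, bic = c("mixture", "hard")) {
  bic <- match.arg(bic)
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  k_range <- sort(unique(pmin(pmax(k_range, hc$k_min), n)))
  rows <- vector("list", length(k_range))
  labs <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    lab <- cut_ward(hc, k)
    flagged <- FALSE
    if (bic == "mixture") {
      bm <- bic_spherical_mixture(X, lab)
      bval <- bm$bic; W <- bm$W
    } else {
      W <- within_ss(X, lab)
      if (W <= 0) { W <- n * d * .Machine$double.eps; flagged <- TRUE }
      bval <- n * d * log(W / (n * d)) + log(n) * k * d
    }
    sil <- if (k >= 2 && k < n)
      mean(cluster::silhouette(lab, dist(X))[, "sil_width"]) else NA_real_
    rows[[i]] <- data.frame(k = k, bic = bval, W = W,
                            dunn = dunn_index(X, lab), silhouette = sil,
                            degenerate = flagged)
    labs[[i]] <- lab
  }
  scores <- do.call(rbind, rows)
  best <- which.min(scores$bic)
  structure(list(k = scores$k[best], labels = labs[[best]],
                 scores = scores, merge_history = hc, bic_variant = bic),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: k = %d (BIC-selected from %d candidates)\n",
              x$k, nrow(x$scores)))
  print(utils::head(x$scores[order(x$scores$bic), ], 5))
  invisible(x)
}

#' Delineate fire-regime regions for one period
#'
#' The full regionalization path: transform the six fire variables, fit the
#' correlation-matrix PCA, keep the axes covering `var_threshold` of the
#' variance, cluster the retained scores under queen contiguity with
#' constrained Ward, and select k by BIC.
#'
#' @param regimes a `fire_regimes` table for one period.
#' @param grid the `fire_grid` the table is indexed on.
#' @param drop_season exclude the season-peak variable (five-variable
#'   clustering variant).
#' @param k_range candidate ks (default 1:15).
#' @param var_threshold PCA retention rule (default 0.95).
#' @param contiguity `"queen"` (default) or `"rook"`.
#' @return a `cluster_solution` with extra elements `pca` (the oriented
#'   `pca_model`) and `retained_scores`.
#' @export
cluster_regions <- function(regimes, grid, drop_season = FALSE,
                            k_range = 1:15, var_threshold = 0.95,
                            contiguity = "queen") {
  stopifnot(nrow(regimes) == grid$n_cells)
  regimes <- regimes[order(regimes$cell_id), ]
  pca <- fit_fire_pca(regimes, drop_season = drop_season,
                      var_threshold = var_threshold)
  S <- pca$scores[, seq_len(pca$n_retained), drop = FALSE]
  graph <- build_contiguity(grid, contiguity)
  hc <- constrained_ward(S, graph)
  sol <- select_k(hc, S, k_range)
  sol$pca <- pca
  sol$retained_scores <- S
  sol
}
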