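ANTHROPIC_VARS <- c("anthropic_pct", "change_anthropic_pct",
                    "pop_density", "livestock_density")
CLIMATIC_VARS <- c("t_annual", "t_dry", "p_annual", "p_dry",
                   "peak_dry_season")

#' Random-forest classification accuracy of cluster labels
#'
#' Fits a random forest of `n_trees` trees predicting the fire-regime region
#' label from a covariate set and reports the out-of-bag accuracy with a
#' Clopper-Pearson 95% binomial confidence interval on the OOB correct
#' count, plus the mean-decrease-in-accuracy variable importances.
#'
#' @param X data.frame or matrix of covariates.
#' @param labels factor-coercible cluster labels (>= 2 classes; n >= 30).
#' @param n_trees number of trees (default 500); `sqrt(p)` predictors per
#'   split (the classification default).
#' @param seed RNG seed.
#' @return list: `accuracy`, `ci` (length 2), `n`, `importance` (named,
#'   mean decrease in accuracy), `confusion`.
#' @export
rf_accuracy <- function(X, labels, n_trees = 500, seed = 1) {
  labels <- factor(labels)
  if (length(labels) < 30) stop("rf_accuracy: need n >= 30")
  if (nlevels(labels) < 2) stop("rf_accuracy: need at least two classes")
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(labels))
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = labels, ntree = n_trees,
                                   importance = TRUE)
  pred <- rf$predicted  # OOB predictions
  correct <- sum(pred == labels)
  ci <- binom.test(correct, length(labels))$conf.int
  acc <- correct / length(labels)
  imp <- randomForest::importance(rf, type = 1)[, 1]
  list(accuracy = acc, ci = as.numeric(ci), n = length(labels),
       importance = imp, confusion = rf$confusion)
}

#' PCA of anthropic and/or climatic covariates
#'
#' Correlation-matrix PCA of one covariate set, with `ln(x + 1)` applied to
#' the population and livestock densities (heavy-tailed by construction) and
#' axes oriented so that higher anthropic presence (anthropic area
#' percentage) scores positive on PC1 of the anthropic set, and higher
#' dry-season temperature scores positive on PC1 of the climatic set.
#'
#' @param table data.frame holding the covariates: the anthropic columns
#'   (`anthropic_pct`, `change_anthropic_pct`, `pop_density`,
#'   `livestock_density`), the climatic columns (`t_annual`, `t_dry`,
#'   `p_annual`, `p_dry`, `peak_dry_season`), or both.
#' @param set `"anthropic"`, `"climatic"`, or `"both"`.
#' @param var_threshold axis retention rule.
#' @return an oriented `pca_model`.
#' @export
fit_covariate_pca <- function(table, set = c("anthropic", "climatic", "both"),
                              var_threshold = 0.95) {
  set <- match.arg(set)
  vars <- switch(set, anthropic = ANTHROPIC_VARS, climatic = CLIMATIC_VARS,
                 both = c(ANTHROPIC_VARS, CLIMATIC_VARS))
  missing <- setdiff(vars, names(table))
  if (length(missing))
    stop("missing covariate columns: ", paste(missing, collapse = ", "))
  X <- as.matrix(table[, vars, drop = FALSE])
  for (v in intersect(c("pop_density", "livestock_density"), vars))
    X[, v] <- log1p(X[, v])
  model <- fit_pca(X, var_threshold)
  anchor <- if (set == "climatic") list(PC1 = "t_dry")
            else list(PC1 = "anthropic_pct")
  orient_axes(model, anchor)
}

#' Redundancy analysis of fire variables on covariates
#'
#' Multivariate least squares of the (transformed, standardized) fire
#' variables on a covariate matrix; the constrained variance fraction is
#' \eqn{R^2 = tr(\hat Y^T \hat Y) / tr(Y_c^T Y_c)}, adjusted by the Ezekiel
#' correction \eqn{1 - (1 - R^2)(n - 1)/(n - m - 1)} with `m` the rank of
#' the centred predictors. Significance is assessed by permuting the rows
#' of `X` and recomputing \eqn{R^2}; the p-value is
#' `(1 + #[perm >= obs]) / (1 + n_perm)`, never exactly zero. Aliased
#' (rank-deficient) predictor columns are dropped with a message.
#'
#' @param Y response matrix (e.g. [transform_fire_variables()] output).
#' @param X predictor matrix or data.frame.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return object of class `rda_result`: `r2`, `r2_adj`, `permutation_p`,
#'   `perm_r2` (vector), `axis_scores` (site scores on constrained axes),
#'   `axis_eigenvalues`, `n`, `m`.
#' @export
rda_fire <- function(Y, X, n_perm = 999, seed = 1) {
  Y <- as.matrix(Y); X <- as.matrix(as.data.frame(X))
  stopifnot(nrow(Y) == nrow(X))
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    drop <- colnames(Xc)[qrX$pivot[(qrX$rank + 1):ncol(Xc)]]
    message("dropping aliased predictor(s): ", paste(drop, collapse = ", "))
    Xc <- Xc[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(Xc)
  }
  m <- qrX$rank
  if (n <= m + 1) stop("rda_fire: need n > number of predictors + 1")
  tot <- sum(Yc^2)
  r2_of <- function(Xmat) {
    fit <- qr.fitted(qr(Xmat), Yc)
    sum(fit^2) / tot
  }
  r2 <- r2_of(Xc)
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  set.seed(seed)
  perm_r2 <- vapply(seq_len(n_perm), function(i) {
    r2_of(Xc[sample(n), , drop = FALSE])
  }, numeric(1))
  p <- (1 + sum(perm_r2 >= r2)) / (1 + n_perm)
  fit <- qr.fitted(qrX, Yc)
  sv <- svd(fit)
  n_ax <- min(m, ncol(Yc))
  structure(list(r2 = r2, r2_adj = r2_adj, permutation_p = p,
                 perm_r2 = perm_r2,
                 axis_scores = (sv$u %*% diag(sv$d, length(sv$d)))[,
                   seq_len(n_ax), drop = FALSE],
                 axis_eigenvalues = (sv$d^2 / (n - 1))[seq_len(n_ax)],
                 n = n, m = m),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("rda_result: R2 = %.3f, adj R2 = %.3f, permutation p = %.4g (%d perms)\n",
              x$r2, x$r2_adj, x$permutation_p, length(x$perm_r2)))
  invisible(x)
}

#' Correlation between a fire-activity gradient and an environmental gradient
#'
#' Pearson (with 95% CI) and Spearman correlations between per-cell PC1
#' scores of the fire PCA and of a covariate PCA, with a sign verdict:
#' `"negative"`/`"positive"` when the Pearson CI excludes zero, `"none"`
#' otherwise.
#'
#' @param pc1_fire,pc1_env matched numeric vectors of cell scores.
#' @return list: `pearson`, `pearson_ci`, `pearson_p`, `spearman`,
#'   `spearman_p`, `sign`, `n`.
#' @export
gradient_relation <- function(pc1_fire, pc1_env) {
  stopifnot(length(pc1_fire) == length(pc1_env))
  if (length(pc1_fire) < 3) stop("gradient_relation: need n >= 3")
  pt <- cor.test(pc1_env, pc1_fire, method = "pearson")
  st <- suppressWarnings(cor.test(pc1_env, pc1_fire, method = "spearman"))
  ci <- as.numeric(pt$conf.int)
  sgn <- if (ci[1] > 0) "positive" else if (ci[2] < 0) "negative" else "none"
  list(pearson = unname(pt$estimate), pearson_ci = ci,
       pearson_p = pt$p.value, spearman = unname(st$estimate),
       spearman_p = st$p.value, sign = sgn, n = length(pc1_fire))
}
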