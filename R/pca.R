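FIRE_LOG_VARS <- c("n_fires", "size_q50_ha", "size_q99_ha",
                   "burned_area_norm", "frequency_q99")
FIRE_VARS <- c(FIRE_LOG_VARS, "season_peak_month")

#' Transform fire-regime variables for ordination
#'
#' Applies `ln(x + 1)` to the five activity variables (fire count, median
#' and 99th-percentile size, normalized burned area, frequency) seeking
#' normality; the season peak is left on the month scale. Columns are then
#' z-standardized (mean 0, sd 1).
#'
#' @param regimes a `fire_regimes` table ([regime_table()]), imputation
#'   already applied (no missing values).
#' @param drop_season if `TRUE`, omit the season-peak column (five-variable
#'   variant).
#' @param standardize z-standardize columns (default `TRUE`).
#' @return numeric matrix (cells x variables) with attributes
#'   `log_center`/`log_scale` when standardized; row order follows
#'   `regimes$cell_id`.
#' @export
transform_fire_variables <- function(regimes, drop_season = FALSE,
                                     standardize = TRUE) {
  vars <- if (drop_season) FIRE_LOG_VARS else FIRE_VARS
  stopifnot(all(vars %in% names(regimes)))
  X <- as.matrix(regimes[, vars, drop = FALSE])
  if (anyNA(X)) stop("missing values in fire variables; impute first")
  if (any(X[, intersect(vars, FIRE_LOG_VARS), drop = FALSE] < 0))
    stop("negative values in fire activity variables")
  for (v in intersect(vars, FIRE_LOG_VARS)) X[, v] <- log1p(X[, v])
  if (standardize) {
    ctr <- colMeans(X); scl <- apply(X, 2, sd)
    if (any(scl == 0))
      stop("constant column(s): ", paste(names(scl)[scl == 0], collapse = ", "))
    X <- scale(X, ctr, scl)
    attr(X, "log_center") <- ctr
    attr(X, "log_scale") <- scl
  }
  rownames(X) <- regimes$cell_id
  X
}

#' Correlation-matrix principal component analysis
#'
#' Centers and scales the input (equivalently, eigen-decomposes its
#' correlation matrix) and returns loadings, eigenvalues, variance
#' fractions, scores, and the number of axes retained as the smallest
#' prefix whose cumulative variance fraction reaches `var_threshold`.
#'
#' @param X numeric matrix, observations in rows; no missing values and
#'   more rows than columns.
#' @param var_threshold cumulative-variance retention rule (default 0.95).
#' @return object of class `pca_model`: `loadings` (orthonormal columns),
#'   `eigenvalues` (non-increasing), `variance_fraction`, `center`, `scale`
#'   (of the input space), `scores`, `n_retained`, `variable_names`.
#' @export
fit_pca <- function(X, var_threshold = 0.95) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("fit_pca: missing values")
  if (nrow(X) <= ncol(X)) stop("fit_pca: need more observations than variables")
  scl <- apply(X, 2, sd)
  if (any(scl == 0))
    stop("constant column(s): ",
         paste(colnames(X)[scl == 0], collapse = ", "))
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  vf <- ev / sum(ev)
  model <- list(
    variable_names = colnames(X),
    center = pc$center, scale = pc$scale,
    loadings = pc$rotation, eigenvalues = ev,
    variance_fraction = vf,
    scores = pc$x,
    n_retained = which(cumsum(vf) >= var_threshold)[1],
    log_center = attr(X, "log_center"),
    log_scale = attr(X, "log_scale"))
  class(model) <- "pca_model"
  model
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d variables, %d axes retained (%.1f%% variance)\n",
              length(x$variable_names), x$n_retained,
              100 * sum(x$variance_fraction[seq_len(x$n_retained)])))
  invisible(x)
}

#' Fix the sign of PCA axes by anchor variables
#'
#' A PCA axis is defined up to sign; this orients axes so that named anchor
#' variables load with a requested sign, making score gradients reproducible
#' (e.g. higher PC1 = more fire activity). If an anchor loading is exactly
#' zero, the variable with the largest absolute loading on that axis is used
#' instead (with a message).
#'
#' @param model a `pca_model`.
#' @param anchors named list: names are axis labels (`"PC1"`, `"PC2"`, ...),
#'   values are variable names; each axis is flipped so the anchor's loading
#'   is positive (or matches `signs`).
#' @param signs requested signs, recycled over anchors (default +1).
#' @return the reoriented `pca_model` (loadings and scores flipped in step;
#'   eigenvalues and variance fractions untouched).
#' @export
orient_axes <- function(model, anchors, signs = 1) {
  stopifnot(inherits(model, "pca_model"))
  signs <- rep_len(signs, length(anchors))
  for (i in seq_along(anchors)) {
    ax <- names(anchors)[i]
    if (!ax %in% colnames(model$loadings)) next
    v <- anchors[[i]]
    if (!v %in% model$variable_names)
      stop(sprintf("anchor variable '%s' not in model", v))
    l <- model$loadings[v, ax]
    if (l == 0) {
      v2 <- model$variable_names[which.max(abs(model$loadings[, ax]))]
      message(sprintf("axis %s: zero anchor loading for '%s'; using '%s'",
                      ax, v, v2))
      l <- model$loadings[v2, ax]
    }
    if (sign(l) != sign(signs[i])) {
      model$loadings[, ax] <- -model$loadings[, ax]
      model$scores[, ax] <- -model$scores[, ax]
    }
  }
  model
}

#' Fit the fire-variable PCA for one period
#'
#' Convenience wrapper: [transform_fire_variables()] then [fit_pca()] then
#' [orient_axes()] with the default anchors (burned area positive on PC1 so
#' PC1 is a fire-activity gradient; season peak positive on PC2).
#'
#' @inheritParams transform_fire_variables
#' @param var_threshold see [fit_pca()].
#' @return oriented `pca_model`; `log_center`/`log_scale` carry the
#'   log-space standardization so later periods can be projected.
#' @export
fit_fire_pca <- function(regimes, drop_season = FALSE, var_threshold = 0.95) {
  X <- transform_fire_variables(regimes, drop_season = drop_season,
                                standardize = FALSE)
  model <- fit_pca(X, var_threshold)
  anchors <- list(PC1 = "burned_area_norm")
  if (!drop_season) anchors$PC2 <- "season_peak_month"
  orient_axes(model, anchors)
}

#' Project fire-regime data onto a previously fitted PCA space
#'
#' Applies the reference model's variable transforms, centering and scaling,
#' then its loadings — no refitting — so scores of different periods are
#' directly comparable in the reference (first-period) component space.
#' Projecting the data the model was fitted on reproduces its scores
#' exactly.
#'
#' @param model a `pca_model` fitted on fire variables (via
#'   [fit_fire_pca()] or [fit_pca()] on a transformed matrix).
#' @param regimes a `fire_regimes` table, or a numeric matrix already in the
#'   model's input space (same variable set).
#' @return matrix of projected scores (cells x axes).
#' @export
project_onto <- function(model, regimes) {
  stopifnot(inherits(model, "pca_model"))
  if (is.data.frame(regimes)) {
    drop_season <- !"season_peak_month" %in% model$variable_names
    X <- transform_fire_variables(regimes, drop_season = drop_season,
                                  standardize = FALSE)
  } else X <- as.matrix(regimes)
  if (!identical(colnames(X), model$variable_names))
    stop("variable set does not match the reference model")
  Xs <- scale(X, model$center, model$scale)
  S <- Xs %*% model$loadings
  rownames(S) <- rownames(X)
  S
}
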