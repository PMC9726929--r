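#' Train a quantile regression forest
#'
#' Bagged regression trees with per-split feature subsampling (`mtry`) whose
#' leaves retain the in-bag training targets, so the fitted forest yields
#' both mean and conditional-quantile dose predictions. The
#' `"random_threshold"` split rule (the "extratrees" rule) draws one uniform
#' threshold between the feature's min and max within the node for each of
#' the `mtry` candidate features and keeps the best by variance reduction;
#' `"variance"` is the classical exhaustive CART search.
#'
#' @param x A `model_matrix` from [encode_features()], or a numeric feature
#'   matrix (then `y` is required).
#' @param y Numeric target (dose, Gy) when `x` is a plain matrix.
#' @param n_trees Number of trees.
#' @param mtry Features considered per split; values above the feature count
#'   are clamped with a warning. Default: a third of the features, rounded up.
#' @param min_node_size Minimum targets per leaf.
#' @param split_rule `"random_threshold"` or `"variance"`.
#' @param bag Bootstrap-resample rows per tree (`TRUE`, standard bagging);
#'   `FALSE` grows every tree on the full sample (no out-of-bag rows).
#' @param importance Compute out-of-bag permutation importance per feature.
#' @param seed Integer seed; forests are reproducible given seed, data and
#'   hyperparameters.
#' @return An object of class `quantile_forest`.
#' @export
train_quantile_forest <- function(x, y = NULL, n_trees = 500, mtry = NULL,
                                  min_node_size = 1,
                                  split_rule = c("random_threshold", "variance"),
                                  bag = TRUE, importance = FALSE,
                                  seed = NULL) {
  split_rule <- match.arg(split_rule)
  if (inherits(x, "model_matrix")) { y <- x$dose; x <- x$features }
  x <- as.matrix(x)
  if (is.null(y)) stop("target y required")
  if (nrow(x) < 2) stop("need at least 2 rows")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, ceiling(p / 3))
  if (mtry > p) {
    warning("mtry exceeds feature count; clamped to ", p)
    mtry <- p
  }
  if (!is.null(seed)) set.seed(seed)
  cpp <- .qf_train_cpp(x, as.numeric(y), as.integer(n_trees),
                       as.integer(mtry), as.integer(min_node_size),
                       split_rule == "random_threshold", bag, importance)
  imp <- cpp$importance
  if (!is.null(imp)) names(imp) <- colnames(x)
  out <- list(cpp = cpp, registry = colnames(x),
              y_range = range(y), n = nrow(x),
              params = list(n_trees = n_trees, mtry = mtry,
                            min_node_size = min_node_size,
                            split_rule = split_rule, bag = bag),
              importance = imp, seed = seed)
  class(out) <- "quantile_forest"
  out
}

#' @export
print.quantile_forest <- function(x, ...) {
  cat(sprintf(
    "quantile forest: %d trees, mtry = %d, min_node_size = %d, %s splits, n = %d\n",
    x$params$n_trees, x$params$mtry, x$params$min_node_size,
    x$params$split_rule, x$n))
  invisible(x)
}

qf_newdata <- function(model, rows) {
  if (inherits(rows, "model_matrix")) rows <- rows$features
  rows <- as.matrix(rows)
  if (is.null(colnames(rows))) {
    if (ncol(rows) != length(model$registry))
      stop("feature columns do not match the training registry")
  } else {
    if (!all(model$registry %in% colnames(rows)))
      stop("feature columns do not match the training registry: missing ",
           paste(setdiff(model$registry, colnames(rows)), collapse = ", "))
    rows <- rows[, model$registry, drop = FALSE]
  }
  storage.mode(rows) <- "double"
  rows
}

#' Mean dose predictions from a quantile forest
#'
#' Average over trees of the leaf mean reached by each row. Because every
#' leaf mean lies within the training target range, predictions cannot
#' extrapolate beyond the doses seen in training.
#'
#' @param model A [train_quantile_forest()] fit.
#' @param rows New rows (`model_matrix`, matrix or data.frame) with the
#'   training feature columns.
#' @return Numeric vector of dose estimates (Gy).
#' @export
predict_mean <- function(model, rows) {
  stopifnot(inherits(model, "quantile_forest"))
  .qf_predict_mean_cpp(model$cpp, qf_newdata(model, rows))
}

#' Quantile dose predictions from a quantile forest
#'
#' Weighted empirical quantiles of the leaf-stored training targets pooled
#' across trees (each leaf's targets carry weight `1 / (leaf size * trees)`),
#' the quantile-regression-forest construction. Non-decreasing in `tau` for
#' every row.
#'
#' @inheritParams predict_mean
#' @param taus Quantile levels in (0, 1).
#' @return Numeric matrix, one column per `tau` (named `q<tau>`).
#' @export
predict_quantiles <- function(model, rows,
                              taus = c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95)) {
  stopifnot(inherits(model, "quantile_forest"))
  if (any(taus <= 0 | taus >= 1)) stop("taus must be in (0, 1)")
  out <- .qf_predict_quantiles_cpp(model$cpp, qf_newdata(model, rows),
                                   as.numeric(taus))
  colnames(out) <- paste0("q", taus)
  attr(out, "taus") <- taus
  out
}

#' @export
predict.quantile_forest <- function(object, newdata, taus = NULL, ...) {
  if (is.null(taus)) predict_mean(object, newdata)
  else predict_quantiles(object, newdata, taus)
}
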