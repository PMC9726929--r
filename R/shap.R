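# resolve a prediction function for the model types used in this package
predict_any <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "quantile_forest"))
    return(function(x) predict_mean(model, x))
  if (inherits(model, "learner_fit"))
    return(function(x) predict_learner(model, x))
  stop("unsupported model type; pass a function(x) -> predictions")
}

#' Exact Shapley attribution of dose predictions
#'
#' Computes exact Shapley values by enumerating all feature subsets. The
#' value function is interventional: `v(S)` is the model prediction averaged
#' over a background sample in which the features in `S` are replaced by the
#' explained row's values and the rest keep their background values. Each
#' feature's Shapley value averages its marginal contribution
#' `v(S + i) - v(S)` over subsets, weighted by `|S|!(|F|-|S|-1)!/|F|!`.
#' Attributions are in Gy and satisfy local accuracy:
#' `base + sum(shap) = f(x)` for every explained row.
#'
#' @param model A `quantile_forest`, `learner_fit`, or a prediction
#'   `function(matrix) -> numeric`.
#' @param explain_rows Matrix (or `model_matrix`) of rows to explain.
#' @param background_rows Background reference sample (same columns);
#'   typically ~100 training rows.
#' @param max_features Enumeration guard: more features than this is an
#'   error (use a sampling approximation outside this package).
#' @return A list of class `shap_matrix`: `shap` (rows x features, Gy),
#'   `base_value` (mean background prediction), `prediction` (per row),
#'   `features`.
#' @export
exact_shap <- function(model, explain_rows, background_rows,
                       max_features = 10) {
  f <- predict_any(model)
  if (inherits(explain_rows, "model_matrix")) explain_rows <- explain_rows$features
  if (inherits(background_rows, "model_matrix")) background_rows <- background_rows$features
  X <- as.matrix(explain_rows)
  B <- as.matrix(background_rows)
  if (nrow(B) == 0) stop("background must be non-empty")
  p <- ncol(X)
  if (p > max_features)
    stop("more than ", max_features, " features: exact subset enumeration is ",
         "infeasible; use a sampling-based SHAP approximation instead")
  n_mask <- 2^p
  masks <- 0:(n_mask - 1)
  popcount <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1, 0:(p - 1))) > 0),
                     numeric(1))
  # subset weight |S|!(|F|-|S|-1)!/|F|! (undefined for the full set, which
  # never appears as an S in the sums)
  w <- ifelse(popcount < p,
              factorial(popcount) * factorial(pmax(p - popcount - 1, 0)) /
                factorial(p),
              0)
  nb <- nrow(B)
  shap <- matrix(0, nrow(X), p, dimnames = list(NULL, colnames(X)))
  base <- mean(f(B))
  pred <- f(X)
  for (r in seq_len(nrow(X))) {
    # one prediction call over all 2^p hybrid backgrounds
    big <- B[rep(seq_len(nb), n_mask), , drop = FALSE]
    for (m in masks) {
      if (m == 0) next
      rows <- (m * nb + 1):((m + 1) * nb)
      in_s <- which(bitwAnd(m, bitwShiftL(1, 0:(p - 1))) > 0)
      big[rows, in_s] <- matrix(X[r, in_s], nb, length(in_s), byrow = TRUE)
    }
    v <- colMeans(matrix(f(big), nb, n_mask))
    for (i in seq_len(p)) {
      bit <- bitwShiftL(1, i - 1)
      s_wo <- masks[bitwAnd(masks, bit) == 0]
      shap[r, i] <- sum(w[s_wo + 1] * (v[s_wo + bit + 1] - v[s_wo + 1]))
    }
  }
  out <- list(shap = shap, base_value = base, prediction = pred,
              features = colnames(X))
  class(out) <- "shap_matrix"
  out
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("shap_matrix: %d rows, base value %.3f Gy\n", nrow(x$shap),
              x$base_value))
  print(mean_abs_shap(x))
  invisible(x)
}

#' Mean absolute Shapley importance
#'
#' Ranks features by the mean of |SHAP| over the explained rows (in Gy),
#' descending, with ties broken alphabetically.
#'
#' @param shap A [exact_shap()] result.
#' @return Named numeric vector, most important feature first.
#' @export
mean_abs_shap <- function(shap) {
  stopifnot(inherits(shap, "shap_matrix"))
  m <- colMeans(abs(shap$shap))
  m[order(-m, names(m))]
}

#' Individual conditional expectation (ICE) and partial dependence
#'
#' Sweeps one feature over a grid while holding every other feature at its
#' observed value, per row (ICE curves); the partial dependence curve is the
#' pointwise mean of the ICE curves.
#'
#' @param model As in [exact_shap()].
#' @param rows Matrix or `model_matrix` of observations.
#' @param feature Feature name to sweep.
#' @param grid Numeric grid of feature values; defaults to 25 points spanning
#'   the observed range.
#' @return A list of class `pd_result`: `feature`, `grid`, `ice`
#'   (rows x grid predictions, Gy), `pd` (mean curve).
#' @export
ice_curves <- function(model, rows, feature, grid = NULL) {
  f <- predict_any(model)
  if (inherits(rows, "model_matrix")) rows <- rows$features
  X <- as.matrix(rows)
  if (!feature %in% colnames(X)) stop("unknown feature: ", feature)
  if (is.null(grid))
    grid <- seq(min(X[, feature]), max(X[, feature]), length.out = 25)
  ice <- vapply(grid, function(g) {
    Xg <- X
    Xg[, feature] <- g
    f(Xg)
  }, numeric(nrow(X)))
  ice <- matrix(ice, nrow = nrow(X))
  out <- list(feature = feature, grid = grid, ice = ice, pd = colMeans(ice))
  class(out) <- "pd_result"
  out
}

#' Two-dimensional partial dependence surface
#'
#' As [ice_curves()] for a pair of features: predictions averaged over rows
#' on the cross product of the two grids.
#'
#' @inheritParams ice_curves
#' @param feature_pair Character vector of two feature names.
#' @param grids Optional list of two numeric grids.
#' @return A list of class `pd_result`: `feature` (the pair), `grid` (list of
#'   two), `surface` (matrix, grid1 x grid2, mean predicted dose in Gy).
#' @export
pd_surface_2d <- function(model, rows, feature_pair, grids = NULL) {
  f <- predict_any(model)
  if (inherits(rows, "model_matrix")) rows <- rows$features
  X <- as.matrix(rows)
  if (length(feature_pair) != 2 || !all(feature_pair %in% colnames(X)))
    stop("feature_pair must name two features present in rows")
  if (is.null(grids))
    grids <- lapply(feature_pair, function(ft)
      seq(min(X[, ft]), max(X[, ft]), length.out = 15))
  surface <- matrix(NA_real_, length(grids[[1]]), length(grids[[2]]))
  for (i in seq_along(grids[[1]])) {
    for (j in seq_along(grids[[2]])) {
      Xg <- X
      Xg[, feature_pair[1]] <- grids[[1]][i]
      Xg[, feature_pair[2]] <- grids[[2]][j]
      surface[i, j] <- mean(f(Xg))
    }
  }
  out <- list(feature = feature_pair, grid = grids, surface = surface)
  class(out) <- "pd_result"
  out
}

#' @export
print.pd_result <- function(x, ...) {
  cat("partial dependence for", paste(x$feature, collapse = " x "), "\n")
  invisible(x)
}
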