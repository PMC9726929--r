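#' Specify a dose-reconstruction learner
#'
#' A light wrapper naming a model family and its hyperparameters, so that
#' cross-validation, grid search and ablation code can treat the quantile
#' forest and the baseline learners uniformly. The quantile forest is this
#' package's own implementation; the baselines delegate to the standard
#' packages (`stats::lm`, `glmnet`, `e1071::svm`, `xgboost`, and an
#' `rpart`-partitioned model tree with per-leaf linear fits).
#'
#' @param family One of `"quantile_forest"`, `"boosted_trees"`, `"linear"`,
#'   `"elastic_net"`, `"support_vector"`, `"linear_tree"`.
#' @param hyperparameters Named list; unknown names for a family are an error.
#' @param seed Integer seed used at fit time.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("quantile_forest", "boosted_trees", "linear",
                                  "elastic_net", "support_vector",
                                  "linear_tree"),
                       hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  allowed <- switch(family,
    quantile_forest = c("n_trees", "mtry", "min_node_size", "split_rule", "bag"),
    boosted_trees = c("nrounds", "eta", "max_depth", "subsample", "lambda"),
    linear = character(),
    elastic_net = c("alpha", "nfolds"),
    support_vector = c("kernel", "cost", "gamma", "epsilon"),
    linear_tree = c("max_depth", "cp", "min_split"))
  bad <- setdiff(names(hyperparameters), allowed)
  if (length(bad))
    stop("unknown hyperparameters for family '", family, "': ",
         paste(bad, collapse = ", "))
  out <- list(family = family, hyperparameters = hyperparameters,
              seed = as.integer(seed))
  class(out) <- "model_spec"
  out
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters))
    paste(names(x$hyperparameters), unlist(x$hyperparameters), sep = "=",
          collapse = ", ") else "defaults"
  cat(sprintf("model_spec: %s (%s)\n", x$family, hp))
  invisible(x)
}

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("package '", pkg, "' is required for this learner family")
}

#' Fit a learner to a model matrix
#'
#' @param spec A [model_spec()].
#' @param matrix A `model_matrix` from [encode_features()].
#' @return A fitted object of class `learner_fit` usable with
#'   [predict_learner()].
#' @export
fit_learner <- function(spec, matrix) {
  stopifnot(inherits(spec, "model_spec"), inherits(matrix, "model_matrix"))
  x <- matrix$features
  y <- matrix$dose
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  fit <- switch(spec$family,
    quantile_forest = train_quantile_forest(
      x, y,
      n_trees = hp$n_trees %||% 500,
      mtry = hp$mtry %||% min(6, ncol(x)),
      min_node_size = hp$min_node_size %||% 1,
      split_rule = hp$split_rule %||% "random_threshold",
      bag = hp$bag %||% TRUE),
    linear = {
      f <- stats::lm.fit(cbind(1, x), y)
      # aliased coefficients (e.g. complete one-hot groups vs intercept)
      f$coefficients[is.na(f$coefficients)] <- 0
      f
    },
    elastic_net = {
      need_pkg("glmnet")
      glmnet::cv.glmnet(x, y, alpha = hp$alpha %||% 0.5,
                        nfolds = hp$nfolds %||% 10)
    },
    support_vector = {
      need_pkg("e1071")
      e1071::svm(x, y, kernel = hp$kernel %||% "radial",
                 cost = hp$cost %||% 1,
                 gamma = hp$gamma %||% (1 / ncol(x)),
                 epsilon = hp$epsilon %||% 0.1)
    },
    boosted_trees = {
      need_pkg("xgboost")
      xgboost::xgb.train(
        params = list(eta = hp$eta %||% 0.1,
                      max_depth = hp$max_depth %||% 6,
                      subsample = hp$subsample %||% 1,
                      lambda = hp$lambda %||% 1,
                      nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = hp$nrounds %||% 200, verbose = 0)
    },
    linear_tree = fit_linear_tree(x, y, max_depth = hp$max_depth %||% 3,
                                  cp = hp$cp %||% 0.01,
                                  min_split = hp$min_split %||% 20))
  out <- list(family = spec$family, fit = fit, registry = colnames(x),
              spec = spec)
  class(out) <- "learner_fit"
  out
}

# model tree: rpart partitions the feature space, a linear model is fitted
# in each leaf (ridge-stabilized to tolerate constant one-hot columns)
fit_linear_tree <- function(x, y, max_depth, cp, min_split) {
  need_pkg("rpart")
  df <- data.frame(y = y, x, check.names = TRUE)
  tree <- rpart::rpart(y ~ ., data = df, method = "anova",
                       control = rpart::rpart.control(
                         maxdepth = max_depth, cp = cp, minsplit = min_split))
  leaf <- tree$where
  fits <- lapply(split(seq_along(y), leaf), function(idx) {
    xs <- x[idx, , drop = FALSE]
    a <- crossprod(cbind(1, xs)) + diag(1e-6, ncol(xs) + 1)
    b <- crossprod(cbind(1, xs), y[idx])
    drop(solve(a, b))
  })
  list(tree = tree, fits = fits, colnames = colnames(x))
}

predict_linear_tree <- function(obj, x) {
  df <- data.frame(x, check.names = TRUE)
  # route rows to leaves, then apply the leaf's linear model
  leaf_ids <- as.character(predict_rpart_where(obj$tree, df))
  vapply(seq_len(nrow(x)), function(i) {
    cf <- obj$fits[[leaf_ids[i]]]
    sum(cf * c(1, x[i, ]))
  }, numeric(1))
}

# rpart predicts values, not node assignments, for new data; recover the leaf
# by matching the predicted leaf mean
predict_rpart_where <- function(tree, df) {
  pred <- predict(tree, newdata = df)
  frame_leaf <- which(tree$frame$var == "<leaf>")
  leaf_means <- tree$frame$yval[frame_leaf]
  frame_leaf[max.col(-abs(outer(pred, leaf_means, "-")))]
}

#' Predict doses from a fitted learner
#'
#' @param fit A [fit_learner()] result.
#' @param rows A `model_matrix`, matrix or data.frame with the training
#'   feature columns.
#' @return Numeric vector of dose predictions (Gy).
#' @export
predict_learner <- function(fit, rows) {
  stopifnot(inherits(fit, "learner_fit"))
  if (inherits(rows, "model_matrix")) rows <- rows$features
  x <- as.matrix(rows)
  if (!is.null(colnames(x)) && all(fit$registry %in% colnames(x)))
    x <- x[, fit$registry, drop = FALSE]
  else if (ncol(x) != length(fit$registry))
    stop("feature columns do not match the training registry")
  switch(fit$family,
    quantile_forest = predict_mean(fit$fit, x),
    linear = drop(cbind(1, x) %*% fit$fit$coefficients),
    elastic_net = drop(predict(fit$fit, newx = x, s = "lambda.min")),
    support_vector = unname(predict(fit$fit, x)),
    boosted_trees = predict(fit$fit, x),
    linear_tree = predict_linear_tree(fit$fit, x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
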