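#' Repeated k-fold cross-validation of a learner
#'
#' Shuffles the rows into `k` folds, fits on `k - 1` folds and scores the
#' held-out fold, and repeats the whole procedure `repeats` times with fresh
#' fold assignments (the standard guard against an unlucky single split).
#' The study design applies this on the training quarter of the data only;
#' the held-out test half never enters CV.
#'
#' @param spec A [model_spec()].
#' @param matrix A `model_matrix`.
#' @param k Number of folds (>= 2).
#' @param repeats Number of repeats.
#' @param seed Integer seed; fold assignments and fits are reproducible.
#' @return An object of class `cv_report`: `folds` (data.frame with `repeat_`,
#'   `fold`, `mae`, `rmse`, `r2`), `summary` (mean and SD per metric) and
#'   `spec`.
#' @export
repeated_cv <- function(spec, matrix, k = 5, repeats = 30, seed = 1L) {
  stopifnot(inherits(matrix, "model_matrix"))
  n <- nrow(matrix$features)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("fewer rows than folds")
  set.seed(seed)
  rows <- list()
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(k), n))
    for (f in seq_len(k)) {
      test_idx <- which(fold == f)
      fit <- fit_learner(spec, mm_rows(matrix, -test_idx))
      pred <- predict_learner(fit, mm_rows(matrix, test_idx))
      act <- matrix$dose[test_idx]
      # fold metrics inline: single-row folds (leave-one-out) have no R2
      r2 <- if (length(act) >= 2 && stats::sd(act) > 0 && stats::sd(pred) > 0)
        stats::cor(act, pred)^2 else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        repeat_ = r, fold = f, mae = mean(abs(act - pred)),
        rmse = sqrt(mean((act - pred)^2)), r2 = r2)
    }
  }
  folds <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("mae", "rmse", "r2"),
    mean = c(mean(folds$mae), mean(folds$rmse), mean(folds$r2, na.rm = TRUE)),
    sd = c(stats::sd(folds$mae), stats::sd(folds$rmse),
           stats::sd(folds$r2, na.rm = TRUE)))
  out <- list(folds = folds, summary = summ, spec = spec, k = k,
              repeats = repeats, seed = seed)
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("repeated CV (%d-fold x %d) for %s\n", x$k, x$repeats,
              x$spec$family))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare learner families under identical repeated CV
#'
#' Runs [repeated_cv()] for each spec with the same folds seed and tabulates
#' mean metrics, highest R-squared first — the screening step that picks the
#' preferred model before hyperparameter tuning.
#'
#' @param specs Named list of [model_spec()]s.
#' @param matrix A `model_matrix`.
#' @inheritParams repeated_cv
#' @return data.frame with one row per model: `model`, `r2`, `rmse`, `mae`.
#' @export
compare_learners <- function(specs, matrix, k = 5, repeats = 5, seed = 1L) {
  rows <- lapply(names(specs), function(nm) {
    cv <- repeated_cv(specs[[nm]], matrix, k = k, repeats = repeats,
                      seed = seed)
    s <- cv$summary
    data.frame(model = nm,
               r2 = s$mean[s$metric == "r2"],
               rmse = s$mean[s$metric == "rmse"],
               mae = s$mean[s$metric == "mae"])
  })
  out <- do.call(rbind, rows)
  out[order(-out$r2), , drop = FALSE]
}

#' Grid search over hyperparameters
#'
#' Exhaustively fits every combination in `grid` on the training matrix and
#' scores RMSE on the evaluation matrix; the lowest RMSE wins, with ties
#' broken in favour of the smaller model (fewer trees/rounds, then shallower,
#' then grid order).
#'
#' @param spec_template A [model_spec()] providing the family, seed and any
#'   fixed hyperparameters.
#' @param grid Named list of hyperparameter value vectors (crossed).
#' @param train_matrix,eval_matrix `model_matrix` objects for fitting and
#'   scoring.
#' @return A list of class `grid_search`: `best_spec`, `results` (data.frame
#'   of combinations and RMSE).
#' @export
grid_search <- function(spec_template, grid, train_matrix, eval_matrix) {
  if (!length(grid)) stop("grid must be non-empty")
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  rmse <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    hp <- utils::modifyList(spec_template$hyperparameters,
                            as.list(combos[i, , drop = FALSE]))
    sp <- model_spec(spec_template$family, hp, seed = spec_template$seed)
    fit <- fit_learner(sp, train_matrix)
    pred <- predict_learner(fit, eval_matrix)
    rmse[i] <- regression_metrics(eval_matrix$dose, pred)$rmse
  }
  size_cols <- intersect(c("n_trees", "nrounds", "max_depth"), names(combos))
  ord <- do.call(order, c(list(rmse), lapply(size_cols, function(cl) combos[[cl]]),
                          list(seq_len(nrow(combos)))))
  best <- ord[1]
  best_hp <- utils::modifyList(spec_template$hyperparameters,
                               as.list(combos[best, , drop = FALSE]))
  out <- list(best_spec = model_spec(spec_template$family, best_hp,
                                     seed = spec_template$seed),
              results = cbind(combos, rmse = rmse))
  class(out) <- "grid_search"
  out
}

#' @export
print.grid_search <- function(x, ...) {
  cat("grid search results (best first shown by RMSE):\n")
  print(x$results[order(x$results$rmse), , drop = FALSE], row.names = FALSE)
  invisible(x)
}
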