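#' Dose-reconstruction performance metrics
#'
#' `MAE = mean(|D - Dhat|)`, `RMSE = sqrt(mean((D - Dhat)^2))`, and two
#' R-squared flavours: the headline `r2_pearson_sq` is the squared Pearson
#' correlation between actual and predicted doses (scale/shift invariant),
#' and `r2_ss = 1 - SSres/SStot` is also reported. Per-dose MAE/RMSE are
#' computed by grouping on the actual dose levels, and the absolute-error
#' distribution is summarized by its median and 75th/80th percentiles.
#'
#' @param actual,predicted Equal-length numeric vectors (Gy).
#' @return A list of class `metrics_report`.
#' @export
regression_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  n <- length(actual)
  if (n < 2) stop("need at least 2 observations")
  if (anyNA(actual) || anyNA(predicted)) stop("NA values in inputs")
  err <- actual - predicted
  abs_err <- abs(err)
  constant <- stats::sd(actual) == 0 || stats::sd(predicted) == 0
  r2p <- if (constant) NA_real_ else stats::cor(actual, predicted)^2
  per_dose <- lapply(split(seq_len(n), actual), function(idx)
    c(n = length(idx), mae = mean(abs_err[idx]),
      rmse = sqrt(mean(err[idx]^2))))
  out <- list(n = n,
              mae = mean(abs_err),
              rmse = sqrt(mean(err^2)),
              r2_pearson_sq = r2p,
              r2_ss = 1 - sum(err^2) / sum((actual - mean(actual))^2),
              r2_undefined = constant,
              per_dose = do.call(rbind, per_dose),
              abs_error_quantiles = stats::quantile(
                abs_err, c(0.5, 0.75, 0.8), names = TRUE))
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d: MAE = %.3f Gy, RMSE = %.3f Gy, R2 (Pearson^2) = %s\n",
              x$n, x$mae, x$rmse,
              if (x$r2_undefined) "undefined" else sprintf("%.3f", x$r2_pearson_sq)))
  invisible(x)
}

#' Coverage of actual doses by predicted quantile intervals
#'
#' Counts actual doses `d` with `q_lo <= d <= q_hi` (inclusive) using the
#' requested quantile columns of a [predict_quantiles()] matrix.
#'
#' @param actual Actual doses (Gy).
#' @param quantile_matrix Matrix from [predict_quantiles()] (columns
#'   `q<tau>`).
#' @param tau_lo,tau_hi Interval quantile levels, `tau_lo < tau_hi`.
#' @return A list of class `coverage_report`: `tau_lo`, `tau_hi`, `count`,
#'   `fraction`, `n`.
#' @export
quantile_coverage <- function(actual, quantile_matrix, tau_lo, tau_hi) {
  if (tau_lo >= tau_hi) stop("tau_lo must be < tau_hi")
  cl <- paste0("q", tau_lo); ch <- paste0("q", tau_hi)
  if (!all(c(cl, ch) %in% colnames(quantile_matrix)))
    stop("requested taus absent from quantile matrix")
  if (length(actual) != nrow(quantile_matrix)) stop("length mismatch")
  inside <- actual >= quantile_matrix[, cl] & actual <= quantile_matrix[, ch]
  out <- list(tau_lo = tau_lo, tau_hi = tau_hi, count = sum(inside),
              fraction = mean(inside), n = length(actual))
  class(out) <- "coverage_report"
  out
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("%d of %d actual doses (%.1f%%) within the %g-%g quantile interval\n",
              x$count, x$n, 100 * x$fraction, x$tau_lo, x$tau_hi))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test on model errors
#'
#' Two-sided signed-rank test of paired differences (zero differences
#' dropped, the Wilcoxon convention): exact null distribution when at most 25
#' non-zero differences remain and there are no rank ties, otherwise the
#' normal approximation with tie and continuity corrections. Used to compare
#' squared dose-reconstruction errors of two models on the same test rows.
#'
#' @param errors_a,errors_b Paired error vectors (e.g. squared errors).
#' @return A list of class `wilcoxon_result`: `statistic` (V, sum of positive
#'   ranks), `p_value`, `n_effective`, `degenerate` (all differences zero).
#' @export
wilcoxon_signed_rank <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b)) stop("paired vectors required")
  d <- errors_a - errors_b
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    out <- list(statistic = 0, p_value = 1, n_effective = 0L,
                degenerate = TRUE)
    class(out) <- "wilcoxon_result"
    return(out)
  }
  if (length(nz) < 6)
    warning("fewer than 6 non-zero differences: test has little power")
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  ties <- any(duplicated(r))
  exact <- length(nz) <= 25 && !ties
  wt <- suppressWarnings(stats::wilcox.test(nz, mu = 0, exact = exact,
                                            correct = TRUE))
  out <- list(statistic = unname(v), p_value = wt$p.value,
              n_effective = length(nz), degenerate = FALSE)
  class(out) <- "wilcoxon_result"
  out
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank: V = %g, p = %.3g (n_eff = %d%s)\n",
              x$statistic, x$p_value, x$n_effective,
              if (x$degenerate) ", degenerate: all differences zero" else ""))
  invisible(x)
}

#' Feature-ablation study with paired significance testing
#'
#' For each removal set, retrains the model without those features on the
#' same training rows, evaluates full and reduced models on the same test
#' rows, and compares their paired squared errors with
#' [wilcoxon_signed_rank()]. `mode = "permute"` instead shuffles the removed
#' columns in the test rows (no retraining), a cheaper but weaker probe.
#'
#' @param matrix A `model_matrix` over all rows.
#' @param removal_sets List of character vectors of feature names; default
#'   removes the raw micronucleus index, both micronucleus indices, and the
#'   dicentric yield — the single-assay comparisons.
#' @param model_spec A [model_spec()].
#' @param splits A [split_data()] assignment (train part fits, test part
#'   scores).
#' @param seed Integer seed.
#' @param mode `"refit"` (default) or `"permute"`.
#' @return A list of class `ablation_result` with per-set entries:
#'   `removed`, `wilcoxon` (statistic, p), metric deltas and both
#'   `metrics_report`s.
#' @export
ablation_study <- function(matrix, removal_sets = list("mi_bn",
                                                       c("mi_bn", "mi_bn_c"),
                                                       "yield"),
                           model_spec = cytodose::model_spec("quantile_forest"),
                           splits, seed = 1L, mode = c("refit", "permute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "model_matrix"),
            inherits(splits, "split_assignment"))
  for (rs in removal_sets) {
    if (!all(rs %in% matrix$registry))
      stop("removal set contains unknown features: ",
           paste(setdiff(rs, matrix$registry), collapse = ", "))
    if (all(matrix$registry %in% rs)) stop("cannot remove all features")
  }
  tr <- which(splits$part == "train")
  te <- which(splits$part == "test")
  spec <- model_spec
  spec$seed <- as.integer(seed)
  full_fit <- fit_learner(spec, mm_rows(matrix, tr))
  full_pred <- predict_learner(full_fit, mm_rows(matrix, te))
  actual <- matrix$dose[te]
  full_err2 <- (actual - full_pred)^2
  full_m <- regression_metrics(actual, full_pred)
  results <- lapply(removal_sets, function(rs) {
    if (mode == "refit") {
      red <- mm_drop(matrix, rs)
      red_fit <- fit_learner(spec, mm_rows(red, tr))
      red_pred <- predict_learner(red_fit, mm_rows(red, te))
    } else {
      set.seed(seed)
      xt <- matrix$features[te, , drop = FALSE]
      for (ft in rs) xt[, ft] <- sample(xt[, ft])
      red_pred <- predict_learner(full_fit, xt)
    }
    red_err2 <- (actual - red_pred)^2
    red_m <- regression_metrics(actual, red_pred)
    wx <- wilcoxon_signed_rank(red_err2, full_err2)
    list(removed = rs, wilcoxon = wx,
         delta_r2 = red_m$r2_pearson_sq - full_m$r2_pearson_sq,
         delta_rmse = red_m$rmse - full_m$rmse,
         delta_mae = red_m$mae - full_m$mae,
         full_metrics = full_m, reduced_metrics = red_m)
  })
  out <- list(results = results, mode = mode, full_metrics = full_m)
  class(out) <- "ablation_result"
  out
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf("ablation (%s): full model RMSE = %.3f Gy, R2 = %.3f\n",
              x$mode, x$full_metrics$rmse, x$full_metrics$r2_pearson_sq))
  for (r in x$results)
    cat(sprintf("  - remove {%s}: dRMSE = %+0.3f, dR2 = %+0.3f, p = %.3g\n",
                paste(r$removed, collapse = ", "), r$delta_rmse, r$delta_r2,
                r$wilcoxon$p_value))
  invisible(x)
}
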