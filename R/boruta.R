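#' Shadow-feature (Boruta-style) all-relevant feature selection
#'
#' Each iteration appends a freshly shuffled "shadow" copy of every feature,
#' trains a random forest with out-of-bag permutation importance on the
#' doubled matrix, and scores a "hit" for every real feature whose importance
#' exceeds the maximum shadow importance. Features whose hit counts are
#' significantly above chance (one-sided binomial test against p = 0.5,
#' Bonferroni-corrected over features) are confirmed; significantly below,
#' rejected; otherwise tentative. Only rejected features should be discarded
#' — tentative ones are retained downstream.
#'
#' @param matrix A `model_matrix`.
#' @param n_iter Number of shadow iterations; below 10 a warning is issued.
#' @param alpha Significance level before Bonferroni correction.
#' @param seed Integer seed.
#' @param n_trees,mtry Forest size per iteration; `mtry` defaults to a third
#'   of the doubled feature count.
#' @return An object of class `boruta_result`: data.frame `decisions`
#'   (`feature`, `hits`, `hit_fraction`, `decision`), plus `n_iterations`,
#'   `alpha`, `correction`.
#' @export
run_boruta <- function(matrix, n_iter = 100, alpha = 0.05, seed = 1L,
                       n_trees = 100, mtry = NULL) {
  stopifnot(inherits(matrix, "model_matrix"))
  x <- matrix$features
  p <- ncol(x)
  if (p < 2) stop("need at least 2 features")
  if (n_iter < 10) warning("n_iter < 10: decisions will be unstable")
  set.seed(seed)
  hits <- integer(p)
  n <- nrow(x)
  for (it in seq_len(n_iter)) {
    shadow <- apply(x, 2, sample)  # re-created (re-shuffled) every iteration
    colnames(shadow) <- paste0("shadow_", colnames(x))
    xa <- cbind(x, shadow)
    fit <- train_quantile_forest(xa, matrix$dose, n_trees = n_trees,
                                 mtry = mtry %||% max(1L, ceiling(2 * p / 3)),
                                 min_node_size = 5,
                                 split_rule = "variance",
                                 importance = TRUE)
    imp <- fit$importance
    hits <- hits + (imp[seq_len(p)] > max(imp[-seq_len(p)]))
  }
  thr <- alpha / p  # Bonferroni over features
  p_up <- stats::pbinom(hits - 1, n_iter, 0.5, lower.tail = FALSE)
  p_dn <- stats::pbinom(hits, n_iter, 0.5)
  decision <- ifelse(p_up < thr, "confirmed",
                     ifelse(p_dn < thr, "rejected", "tentative"))
  out <- list(decisions = data.frame(feature = colnames(x),
                                     hits = as.integer(hits),
                                     hit_fraction = hits / n_iter,
                                     decision = decision,
                                     stringsAsFactors = FALSE),
              n_iterations = n_iter, alpha = alpha,
              correction = "Bonferroni")
  class(out) <- "boruta_result"
  out
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("shadow-feature selection (%d iterations, alpha = %g, %s)\n",
              x$n_iterations, x$alpha, x$correction))
  print(x$decisions, row.names = FALSE)
  invisible(x)
}
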