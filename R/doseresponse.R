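#' Pinball (quantile) loss
#'
#' `sum(r * (tau - (r < 0)))` over residuals `r`; at `tau = 0.5` this equals
#' half the absolute-error sum, whose minimizer is the conditional median.
#'
#' @param residuals Numeric residual vector.
#' @param tau Quantile level in (0, 1).
#' @return Total pinball loss (non-negative scalar).
#' @export
pinball_loss <- function(residuals, tau) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  sum(residuals * (tau - (residuals < 0)))
}

lq_design <- function(dose, degree) {
  X <- cbind(1, dose)
  if (degree == 2) X <- cbind(X, dose^2)
  colnames(X) <- c("c", "alpha", if (degree == 2) "beta")
  X
}

#' Quantile linear-quadratic dose-response fit
#'
#' Fits `Q_tau(y | D) = c + alpha * D (+ beta * D^2)` by pinball-loss
#' minimization: a smoothed iteratively reweighted least-squares pass to
#' tolerance 1e-8, followed by an exact vertex polish (quantile-regression
#' optima interpolate `degree + 1` observations, so the polish enumerates
#' candidate interpolation subsets and keeps the loss argmin). Deterministic
#' given the data. When the optimum is non-unique (a degenerate median), the
#' minimum-norm vertex solution is reported and `nonunique` is set.
#'
#' @param dose Dose vector (Gy).
#' @param y Response vector (assay index).
#' @param tau Quantile level; the median (0.5) is the standard choice for
#'   cytogenetic dose-response curves.
#' @param degree 1 (linear) or 2 (linear-quadratic).
#' @return An object of class `lq_fit`: `coef` (named `c`, `alpha`, and for
#'   degree 2 `beta`), `loss`, `tau`, `degree`, `n`, `nonunique`.
#' @export
fit_quantile_lq <- function(dose, y, tau = 0.5, degree = 2) {
  stopifnot(length(dose) == length(y))
  if (!degree %in% 1:2) stop("degree must be 1 or 2")
  ok <- is.finite(dose) & is.finite(y)
  dose <- dose[ok]; y <- y[ok]
  if (length(y) < 10) stop("need at least 10 observations")
  if (length(unique(dose)) < degree + 2)
    stop("need at least degree + 2 distinct dose levels")
  X <- lq_design(dose, degree)
  res <- .qr_fit_cpp(X, y, tau)
  coef <- drop(res$coef)
  names(coef) <- colnames(X)
  out <- list(coef = coef, loss = res$loss, tau = tau, degree = degree,
              n = length(y), nonunique = res$nonunique)
  class(out) <- "lq_fit"
  out
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("quantile LQ fit (tau = %g, degree = %d, n = %d)\n",
              x$tau, x$degree, x$n))
  cf <- format(signif(x$coef, 4))
  if (!is.null(x$se)) {
    cat(paste0("  ", names(x$coef), " = ", cf, " +/- ",
               format(signif(x$se, 3)), collapse = "\n"), "\n")
    if (!is.na(x$p_beta)) cat(sprintf("  p(beta = 0) = %.3g\n", x$p_beta))
  } else {
    cat(paste0("  ", names(x$coef), " = ", cf, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Bootstrap inference for quantile LQ coefficients
#'
#' Case-resampling bootstrap: rows are resampled with replacement, the fit is
#' repeated, and the SE of each coefficient is the SD of its bootstrap
#' replicates. Two-sided p-values use the normal approximation
#' `2 * pnorm(-|coef/se|)`. Reproducible by seed.
#'
#' @inheritParams fit_quantile_lq
#' @param n_boot Number of bootstrap resamples; below 50 the result carries a
#'   `low_boot` warning flag.
#' @param seed Integer seed.
#' @return An `lq_fit` augmented with `se` (named), `p` (named), `p_beta`
#'   (NA for degree 1), `n_boot`, `boot_coef` (replicate matrix) and
#'   `low_boot`.
#' @export
bootstrap_inference <- function(dose, y, tau = 0.5, degree = 2,
                                n_boot = 1000, seed = 1L) {
  fit <- fit_quantile_lq(dose, y, tau = tau, degree = degree)
  ok <- is.finite(dose) & is.finite(y)
  X <- lq_design(dose[ok], degree)
  set.seed(seed)
  bc <- .qr_boot_cpp(X, y[ok], tau, n_boot)
  colnames(bc) <- colnames(X)
  fit$se <- apply(bc, 2, stats::sd)
  fit$p <- 2 * stats::pnorm(-abs(fit$coef / fit$se))
  fit$p[fit$se == 0] <- ifelse(fit$coef[fit$se == 0] == 0, 1, 0)
  fit$p_beta <- if (degree == 2) unname(fit$p["beta"]) else NA_real_
  fit$n_boot <- n_boot
  fit$boot_coef <- bc
  fit$low_boot <- n_boot < 50
  if (fit$low_boot) warning("n_boot < 50: bootstrap SEs are unreliable")
  fit
}

#' Linear median fit after dropping a non-significant quadratic term
#'
#' Degree-1 convenience wrapper of [fit_quantile_lq()] /
#' [bootstrap_inference()]: once the calibrated linearized index shows a
#' quadratic term statistically consistent with zero, its median dose
#' response is summarized as `c + alpha * D`.
#'
#' @inheritParams bootstrap_inference
#' @param n_boot Bootstrap resamples; 0 skips inference.
#' @return An `lq_fit` of degree 1 (with SEs when `n_boot > 0`).
#' @export
fit_linear_after_drop <- function(dose, y, tau = 0.5, n_boot = 1000,
                                  seed = 1L) {
  if (n_boot > 0) bootstrap_inference(dose, y, tau = tau, degree = 1,
                                      n_boot = n_boot, seed = seed)
  else fit_quantile_lq(dose, y, tau = tau, degree = 1)
}

#' Calibrate the micronucleus linearization constant k
#'
#' Incremental search for the constant `k` in
#' `mi_bn_c = Mi/BN + (1/k) * MN/BN` that linearizes the median dose response:
#' for each `k` in the ascending grid, the index is recomputed, a median LQ
#' quantile regression is fitted, and the quadratic term is tested against
#' zero (bootstrap SE, two-sided normal p). The first `k` whose `beta` is
#' statistically consistent with zero (`p > alpha_stop`) is selected. If no
#' grid value qualifies, the `k` minimizing `|beta/se|` is returned with
#' `converged = FALSE`.
#'
#' @param records Cohort `data.frame` carrying `mn_count` (micronuclei),
#'   `bn_count`, `mono_count` and `dose_gy`.
#' @param k_grid Ascending grid of candidate `k` values (default 10..200 in
#'   steps of 10).
#' @param alpha_stop Significance threshold for "consistent with zero".
#' @param n_boot Bootstrap resamples per grid point.
#' @param seed Integer seed for the bootstrap.
#' @param full_trace If `TRUE` the whole grid is evaluated (useful for
#'   plotting the beta trajectory); otherwise the search stops at selection.
#' @return A list of class `k_calibration`: `k_selected`, `converged`,
#'   `grid`, `trace` (data.frame `k`, `beta`, `se_beta`, `p_beta`),
#'   `alpha_stop`, `stop_rule`.
#' @export
calibrate_k <- function(records, k_grid = seq(10, 200, by = 10),
                        alpha_stop = 0.05, n_boot = 1000, seed = 1L,
                        full_trace = FALSE) {
  if (length(k_grid) == 0) stop("k_grid must be non-empty")
  if (is.unsorted(k_grid)) stop("k_grid must be ascending")
  if (length(unique(records$dose_gy)) < 3)
    stop("need at least 3 dose levels to identify the quadratic term")
  trace <- data.frame(k = numeric(), beta = numeric(), se_beta = numeric(),
                      p_beta = numeric())
  k_selected <- NA_real_
  for (k in k_grid) {
    rec <- compute_indices(records, k = k)
    fit <- bootstrap_inference(rec$dose_gy, rec$mi_bn_c, tau = 0.5,
                               degree = 2, n_boot = n_boot, seed = seed)
    trace <- rbind(trace, data.frame(k = k, beta = unname(fit$coef["beta"]),
                                     se_beta = unname(fit$se["beta"]),
                                     p_beta = fit$p_beta))
    if (is.na(k_selected) && fit$p_beta > alpha_stop) {
      k_selected <- k
      if (!full_trace) break
    }
  }
  converged <- !is.na(k_selected)
  if (!converged) {
    z <- abs(trace$beta / trace$se_beta)
    k_selected <- trace$k[which.min(z)]
  }
  out <- list(k_selected = k_selected, converged = converged,
              grid = k_grid, trace = trace, alpha_stop = alpha_stop,
              stop_rule = sprintf(
                "first k (ascending, steps as given) with two-sided bootstrap p(beta = 0) > %g",
                alpha_stop))
  class(out) <- "k_calibration"
  out
}

#' @export
print.k_calibration <- function(x, ...) {
  cat(sprintf("k calibration: k_selected = %g (%s)\n", x$k_selected,
              if (x$converged) "converged" else "no k qualified; min |beta/se|"))
  print(x$trace, row.names = FALSE)
  invisible(x)
}
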