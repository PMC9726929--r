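test_that("regression metrics follow their definitions", {
  m <- regression_metrics(c(0, 3, 8), c(0, 3, 8))
  expect_equal(m$mae, 0); expect_equal(m$rmse, 0)
  expect_equal(m$r2_pearson_sq, 1)
  m2 <- regression_metrics(c(0, 4), c(1, 3))
  expect_equal(m2$mae, 1); expect_equal(m2$rmse, 1)
  # Pearson-squared R2 is scale/shift invariant, unlike 1 - SSres/SStot
  a <- c(0, 1, 2, 3, 5)
  m3 <- regression_metrics(a, 2 * a + 1)
  expect_equal(m3$r2_pearson_sq, 1)
  expect_gt(m3$mae, 0)
  expect_lt(m3$r2_ss, 1)
  const <- regression_metrics(c(2, 2, 2), c(1, 2, 3))
  expect_true(const$r2_undefined)
  expect_true(is.na(const$r2_pearson_sq))
})

test_that("RMSE >= MAE with equality only for equal absolute errors", {
  set.seed(60)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    act <- runif(n, 0, 8)
    pred <- act + rnorm(n)
    m <- regression_metrics(act, pred)
    expect_gte(m$rmse, m$mae - 1e-12)
  }
  eq <- regression_metrics(c(0, 2, 4), c(1, 3, 3))  # all abs errors = 1
  expect_equal(eq$rmse, eq$mae)
})

test_that("per-dose metrics and error percentiles are reported", {
  act <- rep(c(0, 3, 8), each = 4)
  pred <- act + rep(c(-1, 0, 0.5, 1), 3)
  m <- regression_metrics(act, pred)
  expect_equal(rownames(m$per_dose), c("0", "3", "8"))
  expect_equal(unname(m$per_dose[, "mae"]), rep(0.625, 3))
  expect_equal(names(m$abs_error_quantiles), c("50%", "75%", "80%"))
})

test_that("quantile coverage counts inclusively and widens monotonically", {
  act <- c(1, 2, 3)
  qm <- cbind(q0.25 = c(1, 2.5, 0), q0.75 = c(1, 3.5, 2),
              q0.1 = c(0, 2, -1), q0.9 = c(2, 4, 9))
  cov_in <- quantile_coverage(act, qm, 0.25, 0.75)
  expect_equal(cov_in$count, 1L)  # the boundary row (1 in [1, 1]) is inside
  cov_wide <- quantile_coverage(act, qm, 0.1, 0.9)
  expect_gte(cov_wide$count, cov_in$count)
  degenerate <- cbind(q0.25 = act, q0.75 = act)
  expect_equal(quantile_coverage(act, degenerate, 0.25, 0.75)$fraction, 1)
  miss <- cbind(q0.25 = act + 5, q0.75 = act + 6)
  expect_equal(quantile_coverage(act, miss, 0.25, 0.75)$count, 0L)
  expect_error(quantile_coverage(act, qm, 0.75, 0.25), "tau_lo")
})

test_that("signed-rank test handles degenerate, exact and asymptotic cases", {
  d <- c(0.5, 0.2, 0.1, 0.4, 0.3, 0.6)
  res <- wilcoxon_signed_rank(d, rep(0, 6))
  expect_equal(res$p_value, 2 / 2^6)  # all-positive differences, n = 6
  same <- wilcoxon_signed_rank(d, d)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  # antisymmetric differences put the statistic at the null centre
  anti <- c(1, -1, 2, -2, 3, -3, 4, -4)
  res2 <- wilcoxon_signed_rank(anti, rep(0, 8))
  expect_equal(res2$statistic, 8 * 9 / 4)
  expect_gt(res2$p_value, 0.9)
})

test_that("signed-rank p-values match the enumeration oracle for n <= 12", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 6 || any(duplicated(abs(d)))) next
    res <- wilcoxon_signed_rank(d, rep(0, length(d)))
    expect_equal(res$p_value, wilcoxon_enumeration_oracle(d),
                 tolerance = 1e-12)
  }
  # large-n path stays finite and two-sided
  set.seed(62)
  big <- rnorm(100, mean = 0.3)
  res <- wilcoxon_signed_rank(big, rep(0, 100))
  expect_lt(res$p_value, 0.05)
  expect_gte(res$p_value, 0)
})

test_that("removing an injected noise feature is not significant, removing
           the micronucleus indices is", {
  rec <- small_records(seed = 63)
  mm <- encode_features(rec)
  set.seed(64)
  x <- cbind(mm$features, pure_noise = rnorm(nrow(mm$features)))
  mm_n <- structure(list(features = x, dose = mm$dose, registry = colnames(x)),
                    class = "model_matrix")
  sp <- split_data(rec, seed = 65)
  spec <- model_spec("quantile_forest", list(n_trees = 120, mtry = 6))
  # permutation probe: scrambling an uninformative column leaves the paired
  # errors untouched, scrambling the micronucleus indices degrades them
  abp <- ablation_study(mm_n, list("pure_noise", c("mi_bn", "mi_bn_c")),
                        spec, sp, seed = 66, mode = "permute")
  expect_gt(abp$results[[1]]$wilcoxon$p_value, 0.05)
  expect_lt(abs(abp$results[[1]]$delta_rmse), 0.05)
  expect_lt(abp$results[[2]]$wilcoxon$p_value, 0.05)
  # refit mode: error deltas from dropping noise are negligible, dropping
  # the micronucleus indices is large and significant
  ab <- ablation_study(mm_n, list("pure_noise", c("mi_bn", "mi_bn_c")),
                       spec, sp, seed = 66)
  expect_lt(abs(ab$results[[1]]$delta_rmse), 0.15)
  expect_lt(ab$results[[2]]$wilcoxon$p_value, 0.05)
  expect_gt(ab$results[[2]]$delta_rmse, 0)
  expect_error(ablation_study(mm_n, list(colnames(x)), splits = sp),
               "cannot remove all")
  expect_error(ablation_study(mm_n, list("not_a_feature"), splits = sp),
               "unknown")
})

test_that("permutation-mode ablation also degrades informative features", {
  rec <- small_records(seed = 67)
  mm <- encode_features(rec)
  sp <- split_data(rec, seed = 68)
  ab <- ablation_study(mm, list(c("mi_bn", "mi_bn_c")),
                       model_spec("quantile_forest",
                                  list(n_trees = 100, mtry = 6)),
                       sp, seed = 69, mode = "permute")
  expect_gt(ab$results[[1]]$delta_rmse, 0)
})
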