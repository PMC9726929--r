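test_that("exact SHAP matches brute-force results for a linear model", {
  set.seed(40)
  bg <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x1", "x2")))
  f <- function(m) 2 * m[, 1] + 3 * m[, 2]
  x <- matrix(c(1.5, -0.5), 1, 2, dimnames = list(NULL, c("x1", "x2")))
  sh <- exact_shap(f, x, bg)
  expect_equal(unname(sh$shap[1, "x1"]), 2 * (1.5 - mean(bg[, 1])),
               tolerance = 1e-12)
  expect_equal(unname(sh$shap[1, "x2"]), 3 * (-0.5 - mean(bg[, 2])),
               tolerance = 1e-12)
  expect_equal(sh$base_value, mean(f(bg)), tolerance = 1e-12)
})

test_that("ignored features get exactly zero attribution; |F| = 1 collapses", {
  set.seed(41)
  bg <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  f <- function(m) m[, "a"]^2  # ignores b and c
  x <- matrix(c(2, 5, -5), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  sh <- exact_shap(f, x, bg)
  expect_equal(unname(sh$shap[1, c("b", "c")]), c(0, 0))
  one <- exact_shap(function(m) 3 * m[, 1],
                    matrix(2, 1, 1, dimnames = list(NULL, "a")),
                    matrix(rnorm(8), 8, 1, dimnames = list(NULL, "a")))
  expect_equal(unname(one$shap[1, 1]),
               unname(one$prediction - one$base_value))
})

test_that("exchangeable features receive equal attribution", {
  set.seed(42)
  b <- rnorm(12)
  bg <- cbind(u = b, v = b)  # identical background columns
  f <- function(m) m[, "u"] + m[, "v"]
  x <- matrix(c(1, 1), 1, 2, dimnames = list(NULL, c("u", "v")))
  sh <- exact_shap(f, x, bg)
  expect_equal(unname(sh$shap[1, "u"]), unname(sh$shap[1, "v"]),
               tolerance = 1e-12)
})

test_that("SHAP satisfies local accuracy on a fitted forest", {
  rec <- small_records(seed = 43)
  mm <- encode_features(rec)
  keep <- c("age", "yield", "mi_bn", "mi_bn_c")
  x <- mm$features[, keep]
  qf <- train_quantile_forest(x, mm$dose, n_trees = 40, mtry = 2, seed = 44)
  set.seed(45)
  bg <- x[sample(nrow(x), 30), ]
  ex <- x[1:8, ]
  sh <- exact_shap(qf, ex, bg)
  expect_equal(sh$base_value + rowSums(sh$shap), sh$prediction,
               tolerance = 1e-9)
  # efficiency over the explained set
  expect_equal(mean(rowSums(sh$shap)), mean(sh$prediction) - sh$base_value,
               tolerance = 1e-9)
  expect_error(exact_shap(qf, mm$features[1:2, ], mm$features[1:5, ]),
               "enumeration")
})

test_that("subset enumeration equals the permutation-ordering oracle", {
  set.seed(46)
  p <- 4
  bg <- matrix(rnorm(6 * p), 6, p, dimnames = list(NULL, paste0("f", 1:p)))
  f <- function(m) m[, 1] * m[, 2] + exp(m[, 3] / 4) - 0.5 * m[, 4]
  x <- matrix(rnorm(p), 1, p, dimnames = list(NULL, paste0("f", 1:p)))
  sh <- exact_shap(f, x, bg)
  oracle <- shap_permutation_oracle(f, drop(x), bg)
  expect_equal(unname(sh$shap[1, ]), oracle, tolerance = 1e-12)
})

test_that("mean absolute SHAP ranks the dose markers first on cohort models", {
  rec <- small_records(seed = 47)
  mm <- encode_features(rec)
  keep <- c("age", "race_3", "ethnicity_1", "yield", "mi_bn", "mi_bn_c")
  x <- mm$features[, keep]
  qf <- train_quantile_forest(x, mm$dose, n_trees = 60, mtry = 3, seed = 48)
  set.seed(49)
  bg <- x[sample(nrow(x), 40), ]
  sh <- exact_shap(qf, x[sample(nrow(x), 20), ], bg)
  ranked <- names(mean_abs_shap(sh))
  expect_true(all(c("mi_bn_c", "yield", "mi_bn") %in% ranked[1:4]))
  zero <- list(shap = matrix(0, 3, 2, dimnames = list(NULL, c("a", "b"))),
               base_value = 0, prediction = rep(0, 3), features = c("a", "b"))
  class(zero) <- "shap_matrix"
  expect_equal(unname(mean_abs_shap(zero)), c(0, 0))
})

test_that("ICE and partial dependence behave on constant and fitted models", {
  x <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  flat <- ice_curves(function(m) rep(2, nrow(m)), x, "a")
  expect_true(all(flat$ice == 2))
  expect_equal(flat$pd, rep(2, length(flat$grid)))
  expect_equal(flat$pd, colMeans(flat$ice))
  single <- ice_curves(function(m) m[, "a"], x, "a", grid = 0.5)
  expect_equal(dim(single$ice), c(20L, 1L))
  expect_error(ice_curves(function(m) m[, 1], x, "zzz"), "unknown feature")

  rec <- small_records(seed = 50)
  mm <- encode_features(rec)
  keep <- c("age", "yield", "mi_bn", "mi_bn_c")
  qf <- train_quantile_forest(mm$features[, keep], mm$dose, n_trees = 60,
                              mtry = 2, seed = 51)
  pd <- ice_curves(qf, mm$features[1:40, keep], "mi_bn_c")
  # overall non-decreasing trend of reconstructed dose in the linearized index
  expect_gt(pd$pd[length(pd$pd)], pd$pd[1])
  expect_gt(cor(pd$grid, pd$pd), 0.8)
})

test_that("2-D partial dependence peaks where both assay indices are high", {
  rec <- small_records(seed = 52)
  mm <- encode_features(rec)
  keep <- c("age", "yield", "mi_bn", "mi_bn_c")
  qf <- train_quantile_forest(mm$features[, keep], mm$dose, n_trees = 60,
                              mtry = 2, seed = 53)
  ps <- pd_surface_2d(qf, mm$features[1:30, keep], c("yield", "mi_bn_c"))
  ng <- dim(ps$surface)
  expect_gt(ps$surface[ng[1], ng[2]], ps$surface[1, 1])
  expect_equal(max(ps$surface), ps$surface[ng[1], ng[2]],
               tolerance = 0.15 * diff(range(ps$surface)) + 1e-9)
  flat <- pd_surface_2d(function(m) rep(1, nrow(m)), mm$features[1:10, keep],
                        c("yield", "mi_bn"))
  expect_true(all(flat$surface == 1))
})
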