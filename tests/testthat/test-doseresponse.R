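# brute-force oracle: a pinball-loss optimum over a polynomial design
# interpolates p points, so enumerating every p-subset of the data and
# keeping the loss argmin is exact (independent R implementation)
brute_force_qr <- function(dose, y, tau, degree) {
  X <- cbind(1, dose, if (degree == 2) dose^2)
  p <- ncol(X)
  best <- NULL; best_loss <- Inf
  for (s in utils::combn(length(y), p, simplify = FALSE)) {
    b <- tryCatch(solve(X[s, , drop = FALSE], y[s]), error = function(e) NULL)
    if (is.null(b)) next
    loss <- pinball_loss(y - X %*% b, tau)
    if (loss < best_loss - 1e-12) { best_loss <- loss; best <- b }
  }
  list(coef = best, loss = best_loss)
}

test_that("pinball loss matches its definition", {
  expect_equal(pinball_loss(c(1, -1), 0.5), 1.0)
  expect_equal(pinball_loss(rep(0, 5), 0.3), 0)
  expect_equal(pinball_loss(2, 0.9), 1.8)
  expect_equal(pinball_loss(-2, 0.9), 0.2)
  expect_error(pinball_loss(1, 1.2), "tau")
})

test_that("noise-free polynomials and constants are recovered exactly", {
  dose <- rep(c(0, 3, 4, 8), each = 5)
  y <- 0.2 + 0.1 * dose - 0.01 * dose^2
  fit <- fit_quantile_lq(dose, y, tau = 0.5, degree = 2)
  expect_equal(unname(fit$coef), c(0.2, 0.1, -0.01), tolerance = 1e-9)
  expect_equal(fit$loss, 0, tolerance = 1e-10)

  const <- fit_quantile_lq(dose, rep(5, length(dose)), degree = 2)
  expect_equal(unname(const$coef), c(5, 0, 0), tolerance = 1e-9)

  lin <- fit_quantile_lq(dose, 1 + 2 * dose, degree = 1)
  expect_equal(unname(lin$coef), c(1, 2), tolerance = 1e-9)
  expect_error(fit_quantile_lq(c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4)[1:8], 1:8),
               "10 observations")
  expect_error(fit_quantile_lq(rep(c(0, 1, 2), 5), rnorm(15), degree = 2),
               "distinct dose levels")
})

test_that("the solver matches the subset-enumeration oracle on small instances", {
  set.seed(42)
  for (rep in 1:8) {
    tau <- sample(c(0.25, 0.5, 0.75), 1)
    degree <- sample(1:2, 1)
    dose <- sample(0:8, 12, replace = TRUE)
    while (length(unique(dose)) < degree + 2)
      dose <- sample(0:8, 12, replace = TRUE)
    y <- 0.5 + 0.3 * dose + rnorm(12)
    fit <- fit_quantile_lq(dose, y, tau = tau, degree = degree)
    oracle <- brute_force_qr(dose, y, tau, degree)
    expect_equal(fit$loss, oracle$loss, tolerance = 1e-9)
  }
})

test_that("the solver agrees with quantreg on realistic cohorts", {
  skip_if_not_installed("quantreg")
  # a dose mix heavy enough that all four levels survive the count filter
  rec <- small_records(seed = 12, dose_weights = c(0.2, 0.4, 0.1, 0.3))
  for (v in c("yield", "mi_bn", "mi_bn_c")) {
    fit <- fit_quantile_lq(rec$dose_gy, rec[[v]], tau = 0.5, degree = 2)
    rq <- suppressWarnings(  # rq flags possibly non-unique optima
      quantreg::rq(rec[[v]] ~ rec$dose_gy + I(rec$dose_gy^2), tau = 0.5))
    expect_equal(pinball_loss(rec[[v]] - cbind(1, rec$dose_gy, rec$dose_gy^2)
                              %*% coef(rq), 0.5),
                 fit$loss, tolerance = 1e-8 * (1 + fit$loss))
  }
})

test_that("smoothed IRLS and the exact polish agree on smooth fixtures", {
  set.seed(3)
  dose <- rep(c(0, 2, 4, 6, 8), each = 40)
  y <- 0.1 + 0.05 * dose + 0.002 * dose^2 + rnorm(200, sd = 0.05)
  X <- cbind(1, dose, dose^2)
  irls_only <- cytodose:::.qr_fit_cpp(X, y, 0.5, polish = FALSE)
  polished <- cytodose:::.qr_fit_cpp(X, y, 0.5, polish = TRUE)
  expect_equal(drop(irls_only$coef), drop(polished$coef), tolerance = 1e-6)
})

test_that("fits are equivariant under response scaling and dose shifts", {
  set.seed(8)
  dose <- rep(c(0, 1.5, 3, 4, 6, 8), each = 7)[1:41]
  y <- 0.2 + 0.1 * dose + 0.01 * dose^2 + rnorm(41, sd = 0.1)
  f0 <- fit_quantile_lq(dose, y, degree = 2)
  fs <- fit_quantile_lq(dose, 3 * y, degree = 2)
  expect_equal(unname(fs$coef), unname(3 * f0$coef), tolerance = 1e-7)
  expect_equal(fs$loss, 3 * f0$loss, tolerance = 1e-9)
  # dose shift: the optimum maps to c' = c - 2a + 4b, a' = a - 4b, b' = b;
  # under a degenerate (non-unique) median only the optimal loss is invariant
  fd <- fit_quantile_lq(dose + 2, y, degree = 2)
  X <- cbind(1, dose, dose^2)
  mapped <- c(fd$coef["c"] + 2 * fd$coef["alpha"] + 4 * fd$coef["beta"],
              fd$coef["alpha"] + 4 * fd$coef["beta"],
              fd$coef["beta"])
  expect_equal(pinball_loss(y - drop(X %*% mapped), 0.5), f0$loss,
               tolerance = 1e-9)
  if (!f0$nonunique && !fd$nonunique)
    expect_equal(unname(mapped), unname(f0$coef), tolerance = 1e-6)
})

test_that("no small coefficient perturbation lowers the pinball loss", {
  rec <- small_records(seed = 14)
  fit <- fit_quantile_lq(rec$dose_gy, rec$mi_bn_c, degree = 2)
  X <- cbind(1, rec$dose_gy, rec$dose_gy^2)
  base <- pinball_loss(rec$mi_bn_c - drop(X %*% fit$coef), 0.5)
  for (j in 1:3) for (eps in c(-1e-6, 1e-6)) {
    b <- fit$coef; b[j] <- b[j] + eps
    expect_gte(pinball_loss(rec$mi_bn_c - drop(X %*% b), 0.5), base - 1e-12)
  }
})

test_that("bootstrap inference is seeded, near-zero for noise-free data", {
  dose <- rep(c(0, 3, 4, 8), each = 5)
  y <- 0.2 + 0.1 * dose - 0.005 * dose^2
  fit <- bootstrap_inference(dose, y, degree = 2, n_boot = 200, seed = 4)
  expect_true(all(fit$se < 1e-10))
  expect_lt(fit$p_beta, 1e-10)
  set.seed(31)
  yn <- y + rnorm(20, sd = 0.05)
  f1 <- bootstrap_inference(dose, yn, degree = 2, n_boot = 100, seed = 9)
  f2 <- bootstrap_inference(dose, yn, degree = 2, n_boot = 100, seed = 9)
  expect_identical(f1$se, f2$se)
  expect_warning(bootstrap_inference(dose, y, degree = 2, n_boot = 20,
                                     seed = 1), "n_boot")
})

test_that("the quadratic-term test holds its type-I error for linear truth", {
  set.seed(21)
  rejections <- 0L
  for (i in 1:50) {
    dose <- rep(c(0, 2, 4, 8), each = 50)
    y <- 0.2 + 0.1 * dose + rnorm(200, sd = 0.3)
    fit <- bootstrap_inference(dose, y, degree = 2, n_boot = 200,
                               seed = 1000 + i)
    rejections <- rejections + (fit$p_beta < 0.05)
  }
  # binomial 99% upper band around the nominal 5% over 50 simulations
  expect_lte(rejections, 9)
})

test_that("k calibration selects the generating constant", {
  # regenerated with k_true = 30 the closure identity moves with it
  cfg30 <- generator_config(seed = 17, k_true = 30)
  fl <- filter_low_counts(simulate_cohort(cfg30))
  cal <- calibrate_k(fl$records, n_boot = 400, seed = 5)
  expect_equal(cal$k_selected, 30)
  expect_true(cal$converged)
  expect_true(all(diff(cal$trace$k) > 0))
})

test_that("data already linear at the first grid value stops immediately", {
  set.seed(33)
  n <- 400
  dose <- rep(c(0, 3, 4, 8), each = n / 4)
  bn <- rep(1000L, n)
  mn <- rpois(n, bn * (0.02 + 0.004 * dose) * exp(rnorm(n, sd = 0.05)))
  mono <- rpois(n, bn * 0.5)
  rec <- data.frame(dose_gy = dose, bn_count = bn, mn_count = mn,
                    mono_count = mono, mc_count = bn, dic_count = 0)
  cal <- calibrate_k(rec, k_grid = seq(10, 50, 10), n_boot = 300, seed = 6)
  expect_equal(cal$k_selected, 10)
  expect_equal(nrow(cal$trace), 1L)
  expect_error(calibrate_k(rec, k_grid = numeric(0)), "non-empty")
})

test_that("the beta trace changes sign around the selected k", {
  fl <- filter_low_counts(simulate_cohort(generator_config(seed = 19)))
  cal <- calibrate_k(fl$records, k_grid = seq(10, 150, 10), n_boot = 300,
                     seed = 7, full_trace = TRUE)
  expect_gt(cal$trace$beta[1], 0)  # small k under-compensates the turnover
  expect_lt(min(cal$trace$beta), 0)  # large k overshoots
  below <- max(cal$trace$k[cal$trace$beta > 0])
  above <- min(cal$trace$k[cal$trace$beta < 0])
  expect_true(below <= cal$k_selected + 10 && above >= cal$k_selected - 10)
})
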