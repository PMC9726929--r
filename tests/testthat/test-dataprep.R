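test_that("low-count filter uses an inclusive >= 20 boundary and logs reasons", {
  rec <- toy_records()
  rec$bn_count <- c(19, 20, 100, 100)
  rec$mc_count <- c(100, 20, 19, 100)
  out <- filter_low_counts(rec)
  expect_equal(out$filter_log$n_input, 4L)
  expect_equal(out$filter_log$n_retained, 2L)
  expect_equal(out$filter_log$reasons$reason, c("BN", "MC"))
  expect_equal(out$records$bn_count, c(20, 100))
  # idempotence
  again <- filter_low_counts(out$records)
  expect_equal(again$records, out$records)
  expect_equal(again$filter_log$n_excluded, 0L)
  # empty input
  none <- filter_low_counts(rec[0, ])
  expect_equal(none$filter_log$n_input, 0L)
  expect_equal(nrow(none$records), 0L)
  # records without count columns pass through with a warning flag
  expect_warning(thru <- filter_low_counts(rec[, c("donor_id", "dose_gy")]),
                 "absent")
  expect_true(thru$filter_log$counts_missing)
  expect_equal(nrow(thru$records), 4L)
})

test_that("assay indices follow their definitions", {
  rec <- toy_records()[1, ]
  rec$mn_count <- 10; rec$bn_count <- 100; rec$mono_count <- 140
  rec$dic_count <- 5; rec$mc_count <- 100
  out <- compute_indices(rec, k = 70)
  expect_equal(out$mi_bn, 0.100)
  expect_equal(out$mi_bn_c, 0.100 + 140 / 7000)
  expect_equal(out$yield, 0.05)
  # alternative denominator: all scored chromosomes
  expect_equal(compute_indices(rec, k = 70, yield_denominator = "total")$yield,
               5 / 110)
  expect_error(compute_indices(transform(rec, bn_count = 0), k = 70), "zero")
  expect_error(compute_indices(rec, k = 0), "k must be > 0")
})

test_that("the linearized index exceeds the raw index and decreases in k", {
  rec <- small_records(seed = 4)
  expect_true(all(rec$mi_bn_c >= rec$mi_bn))
  expect_true(all((rec$mi_bn_c > rec$mi_bn) == (rec$mono_count > 0)))
  k_small <- compute_indices(rec, k = 30)$mi_bn_c
  k_large <- compute_indices(rec, k = 300)$mi_bn_c
  pos <- rec$mono_count > 0
  expect_true(all(k_small[pos] > k_large[pos]))
  expect_equal(compute_indices(rec, k = 1e12)$mi_bn_c, rec$mi_bn,
               tolerance = 1e-6)
})

test_that("feature encoding one-hots categories and honours the flags", {
  rec <- compute_indices(toy_records(), k = 70)
  mm <- encode_features(rec)
  expect_s3_class(mm, "model_matrix")
  expect_equal(mm$registry,
               c("age", paste0("race_", 0:4), paste0("ethnicity_", 0:2),
                 "yield", "mi_bn", "mi_bn_c"))
  expect_equal(unname(mm$features[1, c("race_3", "race_1", "race_2", "race_4")]),
               c(1, 0, 0, 0))
  expect_true(all(rowSums(mm$features[, paste0("race_", 0:4)]) == 1))
  expect_false(any(c("sex", "dose_rate_category") %in% mm$registry))
  mm2 <- encode_features(rec, include_dose_rate = TRUE, include_sex = TRUE)
  expect_true(all(c("sex", "dose_rate_category") %in% mm2$registry))
  bad <- rec; bad$race[1] <- 9
  expect_error(encode_features(bad), "unknown race")
})

test_that("splits partition rows in the study proportions, stratified by dose", {
  rec <- small_records(seed = 6)
  n <- nrow(rec)
  sp <- split_data(rec, seed = 9)
  expect_equal(length(sp$part), n)
  expect_equal(sum(table(sp$part)), n)
  tab <- table(sp$part)
  expect_equal(unname(tab["test"]), round(0.5 * n), tolerance = 3)
  # stratification: per-dose counts near the stratified targets
  for (d in unique(rec$dose_gy)) {
    nd <- sum(rec$dose_gy == d)
    got <- sum(rec$dose_gy == d & sp$part == "test")
    expect_lte(abs(got - 0.5 * nd), 2)
  }
  expect_identical(split_data(rec, seed = 9)$part, sp$part)
  expect_false(identical(split_data(rec, seed = 10)$part, sp$part))
  all_train <- split_data(rec, fractions = c(1, 0, 0), seed = 1)
  expect_true(all(all_train$part == "train"))
  expect_error(split_data(rec, fractions = c(0.6, 0.6, 0.2)), "sum to 1")
  expect_error(split_data(rec, fractions = c(0.6, 0.6, -0.2)), "non-negative")
})

test_that("a 1122-row table splits into 280/281/561 sized parts", {
  rec <- data.frame(dose_gy = rep(c(0, 3, 4, 8), c(145, 541, 6, 430)))
  sp <- split_data(rec, seed = 1)
  tab <- as.vector(table(sp$part))
  expect_equal(sum(tab), 1122)
  expect_lte(abs(tab[1] - 280), 2)
  expect_lte(abs(tab[2] - 281), 2)
  expect_lte(abs(tab[3] - 561), 2)
})

test_that("the reader remaps deposited-style headers via column_map", {
  coh <- simulate_cohort(small_config(seed = 8))
  attr(coh, "donors") <- NULL
  ext <- coh
  names(ext)[names(ext) == "dose_gy"] <- "Dose"
  names(ext)[names(ext) == "mn_count"] <- "Mi"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(ext, path, row.names = FALSE, quote = FALSE)
  back <- read_cohort(path, column_map = c(dose_gy = "Dose", mn_count = "Mi"))
  expect_equal(back, coh)
  expect_error(read_cohort(path, column_map = c(dose_gy = "NotThere")),
               "NotThere")
  expect_error(read_cohort(withr::local_tempfile(fileext = ".csv")),
               "not found")
})
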