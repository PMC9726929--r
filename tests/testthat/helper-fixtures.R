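# small cohorts for fast unit tests; the default-size cohort is used only
# where a criterion is about the full study design
small_config <- function(seed = 1, ...) {
  generator_config(n_donors = 40, aliquots_per_donor = 6, seed = seed, ...)
}

small_records <- function(seed = 1, k = 70, ...) {
  coh <- simulate_cohort(small_config(seed, ...))
  compute_indices(filter_low_counts(coh)$records, k = k)
}

# noise-free configuration: donor, aliquot and age effects all off
noiseless_config <- function(seed = 1, ...) {
  generator_config(donor_sigma = 0, noise_sigma = 0, age_slope = 0,
                   seed = seed, ...)
}

# deterministic hand-built records for arithmetic checks
toy_records <- function() {
  data.frame(donor_id = c("a", "a", "b", "b"),
             age = c(10, 10, 40, 40), sex = c(0, 0, 1, 1),
             race = c(3, 3, 1, 2), ethnicity = c(0, 1, 2, 2),
             dose_gy = c(0, 3, 3, 8), dose_rate_category = c(0, 1, 2, 3),
             mc_count = c(100, 100, 50, 40), dic_count = c(5, 10, 4, 8),
             bn_count = c(100, 100, 50, 25), mn_count = c(10, 30, 20, 9),
             mono_count = c(140, 300, 400, 600),
             stringsAsFactors = FALSE)
}
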