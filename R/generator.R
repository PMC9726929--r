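#' Assay dose-response parameters
#'
#' Bundle the coefficients of a linear-quadratic (LQ) median dose response
#' `median(y) = c + alpha * D + beta * D^2`, the standard form for cytogenetic
#' aberration yields over the 0--8 Gy range.
#'
#' @param c Baseline (intercept) in index units (events per cell or per
#'   chromosome) at 0 Gy; must be positive.
#' @param alpha Linear coefficient (Gy^-1).
#' @param beta Quadratic coefficient (Gy^-2); negative values encode the
#'   high-dose turnover seen for raw micronucleus indices.
#' @return An object of class `assay_dose_response`.
#' @export
assay_dose_response <- function(c, alpha, beta) {
  stopifnot(is.numeric(c), is.numeric(alpha), is.numeric(beta),
            length(c) == 1L, length(alpha) == 1L, length(beta) == 1L)
  if (c <= 0) stop("baseline `c` must be > 0")
  obj <- list(c = c, alpha = alpha, beta = beta)
  class(obj) <- "assay_dose_response"
  # the median must stay positive over the working dose range
  d <- seq(0, 8, by = 0.1)
  if (any(eval_lq(obj, d) <= 0))
    stop("median curve c + alpha*D + beta*D^2 must be > 0 over D in [0, 8]")
  obj
}

eval_lq <- function(p, dose) p$c + p$alpha * dose + p$beta * dose^2

#' @export
print.assay_dose_response <- function(x, ...) {
  cat(sprintf("LQ dose response: c = %.4g, alpha = %.4g /Gy, beta = %.4g /Gy^2\n",
              x$c, x$alpha, x$beta))
  invisible(x)
}

#' Synthetic cohort generator configuration
#'
#' Defaults emulate the statistical structure of a 155-donor, ~1349-aliquot
#' ex vivo irradiation study: doses 0/3/4/8 Gy mixed in post-filter
#' proportions 145:541:6:430, donor ages 3--69 y (49.1% male), a dicentric
#' yield following an LQ median curve, a raw micronucleus index with a
#' high-dose turnover, and a linearized micronucleus index
#' `Mi/BN + (1/k) * MN/BN` that is linear in dose at the generating constant
#' `k_true`. The mononucleated-cell median is derived from the closure
#' identity `MN/BN = k_true * (mibnc - mibn)`, which makes the generating
#' `k_true` also the linearizing constant.
#'
#' Cell-count distributions are negative binomial with dose-declining means so
#' that heavily irradiated aliquots produce a realistic low-count tail; with
#' the defaults roughly 17% of raw aliquots fail the >= 20 binucleated-cell /
#' >= 20 monocentric-chromosome filters.
#'
#' @param n_donors Number of blood donors.
#' @param aliquots_per_donor Mean aliquots per donor; the cohort holds
#'   `round(n_donors * aliquots_per_donor)` rows assigned round-robin.
#' @param dose_levels Nominal doses in Gy.
#' @param dose_weights Sampling probabilities for `dose_levels`; must sum to 1.
#' @param dca_params,mibn_params [assay_dose_response()] parameters for the
#'   dicentric yield (per monocentric chromosome) and the raw micronucleus
#'   index (per binucleated cell).
#' @param mibnc_intercept,mibnc_slope Linear median dose response of the
#'   linearized micronucleus index (index units and Gy^-1).
#' @param k_true Generating linearization constant (dimensionless, > 0).
#' @param donor_sigma Log-scale SD of donor-level lognormal effects
#'   (median 1, so population medians are preserved).
#' @param donor_corr Correlation of the log donor effects between the DCA and
#'   CBMN assays (shared susceptibility component).
#' @param noise_sigma Log-scale SD of aliquot-level lognormal noise (median 1).
#' @param age_slope Per-year multiplicative age effect on both assay rates;
#'   the multiplier `1 + age_slope * (age - 25)` is floored at 0.5 and
#'   geometrically centred under the age mixture so it does not shift
#'   cohort medians.
#' @param mc_mean0,mc_decline,mc_disp Negative-binomial mean at 0 Gy,
#'   exponential decline rate per Gy, and dispersion (size) for monocentric
#'   chromosome counts.
#' @param bn_mean0,bn_decline,bn_disp Same for binucleated-cell counts.
#' @param race_probs Probabilities of race codes 0..4
#'   (unreported, African American, Asian, White, Mixed).
#' @param ethnicity_probs Probabilities of ethnicity codes 0..2
#'   (unreported, Hispanic/Latino, non-Hispanic/Latino).
#' @param male_fraction Expected fraction of male donors (sex code 0).
#' @param age_range Donor age bounds in years.
#' @param seed Integer seed used by [simulate_cohort()].
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_donors = 155,
                             aliquots_per_donor = 1349 / 155,
                             dose_levels = c(0, 3, 4, 8),
                             dose_weights = c(145, 541, 6, 430) / 1122,
                             dca_params = assay_dose_response(0.0163, 0.00322, 0.00056),
                             mibn_params = assay_dose_response(0.0319, 0.0960, -0.0105),
                             mibnc_intercept = 0.200,
                             mibnc_slope = 0.0945,
                             k_true = 70,
                             donor_sigma = 0.15,
                             donor_corr = 0.1,
                             noise_sigma = 0.12,
                             age_slope = 0.004,
                             mc_mean0 = 800, mc_decline = 0.15, mc_disp = 5,
                             bn_mean0 = 500, bn_decline = 0.38, bn_disp = 3,
                             race_probs = c(0.10, 0.066, 0.16, 0.634, 0.04),
                             ethnicity_probs = c(0.38, 0.24, 0.38),
                             male_fraction = 0.491,
                             age_range = c(3, 69),
                             seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks probability vectors, positivity constraints and the closure
#' identity: the implied mononucleated-to-binucleated median
#' `k_true * (mibnc(D) - mibn(D))` must be strictly positive over 0--8 Gy
#' (a configuration where the linearized index does not exceed the raw index
#' has no valid mononucleated-cell rate and is rejected).
#'
#' @param cfg A `generator_config`.
#' @return `cfg`, invisibly; errors on an invalid configuration.
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_donors < 1) stop("n_donors must be >= 1")
  if (abs(sum(cfg$dose_weights) - 1) > 1e-8) stop("dose_weights must sum to 1")
  if (any(cfg$dose_weights < 0) || all(cfg$dose_weights == 0) ||
      length(cfg$dose_weights) != length(cfg$dose_levels))
    stop("dose_weights must be a non-degenerate probability vector over dose_levels")
  if (any(cfg$dose_levels < 0)) stop("dose_levels must be non-negative")
  if (cfg$k_true <= 0) stop("k_true must be > 0")
  if (cfg$donor_sigma < 0 || cfg$noise_sigma < 0) stop("noise SDs must be >= 0")
  if (abs(cfg$donor_corr) > 1) stop("donor_corr must lie in [-1, 1]")
  if (min(cfg$mc_mean0, cfg$bn_mean0) <= 0 || min(cfg$mc_disp, cfg$bn_disp) <= 0)
    stop("count means and dispersions must be > 0")
  if (abs(sum(cfg$race_probs) - 1) > 1e-8 || any(cfg$race_probs < 0))
    stop("race_probs must be a probability vector")
  if (abs(sum(cfg$ethnicity_probs) - 1) > 1e-8 || any(cfg$ethnicity_probs < 0))
    stop("ethnicity_probs must be a probability vector")
  if (sum(cfg$race_probs > 0) < 2 || sum(cfg$ethnicity_probs > 0) < 2)
    stop("degenerate category probability vectors")
  if (cfg$male_fraction < 0 || cfg$male_fraction > 1)
    stop("male_fraction must be in [0, 1]")
  d <- seq(0, 8, by = 0.1)
  gap <- (cfg$mibnc_intercept + cfg$mibnc_slope * d) - eval_lq(cfg$mibn_params, d)
  if (any(gap <= 0))
    stop("closure check failed: linearized index median must exceed the raw ",
         "micronucleus median over D in [0, 8] (mononucleated rate would be <= 0)")
  invisible(cfg)
}

#' Median dose-response curves implied by a configuration
#'
#' Evaluates the four generating medians at `dose`: dicentric yield,
#' raw micronucleus index `Mi/BN`, linearized index `Mi_BN_c`, and the
#' mononucleated-cell ratio `MN/BN` obtained from the closure identity
#' `MN/BN = k_true * (Mi_BN_c - Mi/BN)`, which guarantees that
#' `Mi/BN + (1/k_true) * MN/BN` reproduces the configured linear median.
#'
#' @param config A [generator_config()].
#' @param dose Dose(s) in Gy, each >= 0.
#' @return A list with numeric vectors `yield_median`, `mibn_median`,
#'   `mibnc_median`, `mn_bn_median`, one element per dose.
#' @export
median_curves <- function(config, dose) {
  validate_generator_config(config)
  if (any(!is.finite(dose)) || any(dose < 0)) stop("dose must be finite and >= 0")
  mibn <- eval_lq(config$mibn_params, dose)
  mibnc <- config$mibnc_intercept + config$mibnc_slope * dose
  list(yield_median = eval_lq(config$dca_params, dose),
       mibn_median = mibn,
       mibnc_median = mibnc,
       mn_bn_median = config$k_true * (mibnc - mibn))
}

#' Generate donor profiles
#'
#' Draws donor demographics (age mixture 50% uniform 3--20 y / 50% uniform
#' 21--69 y, sex, race, ethnicity) and lognormal donor susceptibility
#' multipliers for each assay. The log effects share a common component with
#' correlation `donor_corr` and have log-mean 0, so each multiplier has
#' median exactly 1 and population median curves are preserved.
#'
#' @param config A [generator_config()].
#' @return A data.frame with one row per donor: `donor_id`, `age`, `sex`,
#'   `race`, `ethnicity`, `donor_effect_dca`, `donor_effect_mn`.
#' @export
generate_donors <- function(config) {
  validate_generator_config(config)
  n <- config$n_donors
  lo <- config$age_range[1]; hi <- config$age_range[2]
  mid <- 20  # upper bound of the paediatric stratum
  young <- stats::runif(n) < 0.5
  age <- ifelse(young,
                stats::runif(n, lo, min(mid, hi)),
                stats::runif(n, min(mid + 1, hi), hi))
  age <- round(age)
  sex <- stats::rbinom(n, 1L, 1 - config$male_fraction)  # 0 = male, 1 = female
  race <- sample(0:4, n, replace = TRUE, prob = config$race_probs)
  ethnicity <- sample(0:2, n, replace = TRUE, prob = config$ethnicity_probs)
  rho <- config$donor_corr
  z0 <- stats::rnorm(n); z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  log_dca <- config$donor_sigma * (rho * z0 + sqrt(1 - rho^2) * z1)
  log_mn <- config$donor_sigma * (rho * z0 + sqrt(1 - rho^2) * z2)
  data.frame(donor_id = sprintf("D%03d", seq_len(n)),
             age = pmin(pmax(age, lo), hi),
             sex = sex, race = race, ethnicity = ethnicity,
             donor_effect_dca = exp(log_dca),
             donor_effect_mn = exp(log_mn),
             stringsAsFactors = FALSE)
}

# age multiplier, floored at 0.5 and geometrically centred (mean log = 0
# under the 50/50 paediatric/adult age mixture): with symmetric lognormal
# noise on top, an uncentred skewed multiplier would shift cohort medians by
# its log-mean, biasing every recovered dose-response coefficient
age_multiplier <- function(age, slope, age_range = c(3, 69), mid = 20) {
  raw <- pmax(0.5, 1 + slope * (age - 25))
  g1 <- seq(age_range[1], min(mid, age_range[2]), length.out = 201)
  g2 <- seq(min(mid + 1, age_range[2]), age_range[2], length.out = 201)
  ref_log <- 0.5 * mean(log(pmax(0.5, 1 + slope * (g1 - 25)))) +
    0.5 * mean(log(pmax(0.5, 1 + slope * (g2 - 25))))
  raw / exp(ref_log)
}

#' Generate a raw aliquot cohort table
#'
#' Each aliquot receives a dose sampled from `dose_weights` and a uniformly
#' random dose-rate category 0..4 (unexposed aliquots included: dose rate is
#' undefined at 0 Gy and randomly assigned). Monocentric (MC) and binucleated
#' (BN) cell counts are negative binomial with dose-declining means; event
#' counts are Poisson around `count * rate`, where each rate is the
#' configured median curve scaled by the donor effect, the age multiplier and
#' aliquot-level lognormal noise (all median 1). The micronucleus and
#' mononucleated rates share one CBMN multiplier, so the closure identity
#' `Mi/BN + (1/k_true) * MN/BN = mibnc(D) * multiplier` holds per aliquot up
#' to Poisson discreteness.
#'
#' @param donors Output of [generate_donors()].
#' @param config A [generator_config()].
#' @return A `data.frame` cohort table with columns `donor_id`, `age`, `sex`,
#'   `race`, `ethnicity`, `dose_gy`, `dose_rate_category`, `mc_count`,
#'   `dic_count`, `bn_count`, `mn_count` (micronuclei), `mono_count`
#'   (mononucleated cells).
#' @export
generate_cohort <- function(donors, config) {
  validate_generator_config(config)
  if (nrow(donors) == 0) stop("donors must be non-empty")
  n <- round(config$n_donors * config$aliquots_per_donor)
  di <- rep_len(seq_len(nrow(donors)), n)
  dn <- donors[di, , drop = FALSE]
  dose <- sample(config$dose_levels, n, replace = TRUE, prob = config$dose_weights)
  drc <- sample(0:4, n, replace = TRUE)
  cur <- median_curves(config, dose)
  amult <- age_multiplier(dn$age, config$age_slope, config$age_range)
  e_dca <- exp(config$noise_sigma * stats::rnorm(n))
  e_mn <- exp(config$noise_sigma * stats::rnorm(n))
  mc <- stats::rnbinom(n, size = config$mc_disp,
                       mu = config$mc_mean0 * exp(-config$mc_decline * dose))
  bn <- stats::rnbinom(n, size = config$bn_disp,
                       mu = config$bn_mean0 * exp(-config$bn_decline * dose))
  yield_rate <- cur$yield_median * dn$donor_effect_dca * amult * e_dca
  cbmn_mult <- dn$donor_effect_mn * amult * e_mn
  dic <- pmin(stats::rpois(n, mc * yield_rate), mc)
  mi <- stats::rpois(n, bn * cur$mibn_median * cbmn_mult)
  mono <- stats::rpois(n, bn * cur$mn_bn_median * cbmn_mult)
  data.frame(donor_id = dn$donor_id, age = dn$age, sex = dn$sex,
             race = dn$race, ethnicity = dn$ethnicity,
             dose_gy = dose, dose_rate_category = drc,
             mc_count = mc, dic_count = dic, bn_count = bn,
             mn_count = mi, mono_count = mono,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a full cohort from a configuration
#'
#' Convenience wrapper: seeds the RNG from `config$seed`, generates donors
#' and the aliquot table. Identical configurations give identical tables.
#'
#' @param config A [generator_config()].
#' @return A cohort `data.frame` as from [generate_cohort()], with the donor
#'   table attached as attribute `"donors"`.
#' @export
simulate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  donors <- generate_donors(config)
  cohort <- generate_cohort(donors, config)
  attr(cohort, "donors") <- donors
  cohort
}

#' Write a cohort table to CSV
#'
#' UTF-8, comma-separated, '.' decimal, no row names; round-trips losslessly
#' through [read_cohort()].
#'
#' @param table A cohort `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
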