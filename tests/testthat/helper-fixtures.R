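# Published per-cohort dose-response coefficients (a, b, c) and the
# seasonal quadratics used as generator truth and as fixed model inputs.
reference_dose_response <- function() {
  list(
    "4-10"   = dose_response(21.38, 30.77, 2.42),
    "11-18"  = dose_response(36.15, 17.61, 0.34),
    "19-64"  = dose_response(35.78, 20.26, 0.20),
    "65plus" = dose_response(27.10, 55.92, 0.07)
  )
}

reference_seasonal_rows <- function() {
  tibble::tribble(
    ~cohort,  ~gender,  ~alpha, ~beta, ~gamma, ~peak, ~n,
    "4-10",   "male",    -0.76, 10.97,  22.71,   7.2,  93,
    "4-10",   "female",  -0.43,  7.80,  24.08,   9.1,  74,
    "11-18",  "male",    -0.86, 13.13,   7.49,   7.6, 169,
    "11-18",  "female",  -0.46,  6.94,  23.09,   7.5, 142,
    "19-64",  "male",    -0.65, 10.58,  10.38,   8.1, 333,
    "19-64",  "female",  -0.53,  8.35,  21.16,   7.9, 455,
    "65plus", "male",    -0.34,  5.25,  30.68,   7.7,  90,
    "65plus", "female",  -0.47,  6.87,  23.14,   7.3, 111
  )
}

# Draw n (intake_total, month, serum) triples for one cohort from the
# default generator's distributions: gender x supplement lognormal intake
# mixture, uniform months, additive serum model with calibrated noise.
simulate_serum_points <- function(cohort, n, config, seed) {
  cells <- config$cells[config$cells$cohort == cohort, ]
  withr::with_seed(seed, {
    cell_idx <- sample(nrow(cells), n, replace = TRUE,
                       prob = cells$n_participants)
    takes <- stats::rbinom(n, 1, cells$supplement_prevalence[cell_idx]) == 1
    intake <- vitdfort:::rlnorm_matched(n, 1, 0)  # placeholder, overwritten
    for (i in seq_len(nrow(cells))) {
      ind <- cell_idx == i
      intake[ind] <- vitdfort:::rlnorm_matched(
        sum(ind), cells$intake_mean_nonsupp[i], cells$intake_sd_nonsupp[i])
      add <- ind & takes
      intake[add] <- intake[add] + vitdfort:::rlnorm_matched(
        sum(add), cells$supp_dose_mean[i], cells$supp_dose_sd[i])
    }
    month <- sample.int(12L, n, replace = TRUE)
    serum <- numeric(n)
    for (i in seq_len(nrow(cells))) {
      ind <- cell_idx == i
      serum[ind] <- simulate_serum(intake[ind], month[ind], cohort, config,
                                   gender = cells$gender[i])
    }
    tibble::tibble(intake = intake, serum = serum, month = month)
  })
}

# A tiny generator config (two cells, one cohort) for fast structural tests.
tiny_config <- function(seed = 42, n = 50L, supplement_prevalence = 0.2,
                        blood_sample_fraction = 1, rtec_consumer_fraction = 0.8) {
  cells <- tibble::tibble(
    cohort = "4-10", gender = c("male", "female"),
    n_participants = as.integer(n),
    intake_mean_nonsupp = c(2.03, 1.89), intake_sd_nonsupp = c(0.33, 1.08),
    supplement_prevalence = supplement_prevalence,
    supp_dose_mean = 4, supp_dose_sd = 2,
    rtec_consumer_fraction = rtec_consumer_fraction,
    rtec_mean_g = 31, rtec_sd_g = 18,
    blood_sample_fraction = blood_sample_fraction
  )
  generator_config(
    cells,
    dose_response_params = tibble::tibble(cohort = "4-10", a = 21.38, b = 30.77, c = 2.42),
    seasonal_params = tibble::tibble(cohort = "4-10", gender = c("male", "female"),
                                     alpha = c(-0.76, -0.43), beta = c(10.97, 7.80),
                                     gamma = c(22.71, 24.08)),
    serum_noise_sd = c("4-10" = 15),
    n_psu = 6L, n_strata = 3L, seed = seed
  )
}
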