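#' Configuration of the synthetic survey-cohort generator
#'
#' The generator emulates the statistical structure of a national diet and
#' nutrition survey: four age cohorts (`"4-10"`, `"11-18"`, `"19-64"`,
#' `"65plus"`) crossed with gender, right-skewed (lognormal) dietary and
#' supplemental vitamin D intakes, lognormal ready-to-eat-cereal (RTEC)
#' consumption among consumers, a stratified/clustered sampling frame
#' (strata x primary sampling units), uniform blood-draw months, and serum
#' 25(OH)D composed additively from a cohort-level saturating dose-response
#' curve, a mean-centered quadratic seasonal deviation, and Gaussian noise.
#'
#' @param cells A data frame with one row per cohort x gender cell and
#'   columns `cohort`, `gender`, `n_participants`, `intake_mean_nonsupp`,
#'   `intake_sd_nonsupp`, `supplement_prevalence`, `supp_dose_mean`,
#'   `supp_dose_sd`, `rtec_consumer_fraction`, `rtec_mean_g`, `rtec_sd_g`,
#'   `blood_sample_fraction`.
#' @param dose_response_params Data frame: `cohort`, `a`, `b`, `c` of the
#'   per-cohort saturating curve (see [dose_response()]).
#' @param seasonal_params Data frame: `cohort`, `gender`, `alpha`, `beta`,
#'   `gamma` of the per-cell seasonal quadratic (see [seasonal_fit()]).
#' @param serum_noise_sd Named numeric vector (by cohort) of residual serum
#'   noise, nmol/L.
#' @param n_psu,n_strata Size of the sampling frame; PSUs are spread
#'   round-robin over strata and participants round-robin over PSUs.
#' @param seed Integer seed; mandatory (reproducibility is part of the
#'   contract).
#' @return A validated object of class `generator_config`.
#' @seealso [default_generator_config()] for the packaged calibration,
#'   [generate_cohort()] to draw records.
#' @export
generator_config <- function(cells, dose_response_params, seasonal_params,
                             serum_noise_sd, n_psu = 36L, n_strata = 9L,
                             seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    abort_bad_arg("a seed is mandatory for the generator")
  }
  cells <- tibble::as_tibble(cells)
  needed <- c("cohort", "gender", "n_participants", "intake_mean_nonsupp",
              "intake_sd_nonsupp", "supplement_prevalence", "supp_dose_mean",
              "supp_dose_sd", "rtec_consumer_fraction", "rtec_mean_g",
              "rtec_sd_g", "blood_sample_fraction")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols)) {
    abort_bad_arg("cells is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  for (i in seq_len(nrow(cells))) {
    row <- cells[i, ]
    cell_id <- paste(row$cohort, row$gender)
    fr <- c(row$supplement_prevalence, row$rtec_consumer_fraction, row$blood_sample_fraction)
    if (any(fr < 0 | fr > 1)) {
      abort_bad_arg("cell (%s): fractions must lie in [0, 1]", cell_id)
    }
    pos <- c(row$n_participants, row$intake_mean_nonsupp, row$intake_sd_nonsupp,
             row$supp_dose_mean, row$supp_dose_sd, row$rtec_mean_g, row$rtec_sd_g)
    if (any(pos < 0)) {
      abort_bad_arg("cell (%s): counts, means and s.d. must be nonnegative", cell_id)
    }
  }
  drp <- tibble::as_tibble(dose_response_params)
  if (any(drp$b <= 0) || any(drp$c <= 0)) {
    abort_bad_arg("dose_response_params must have b > 0 and c > 0 in every cohort")
  }
  ssp <- tibble::as_tibble(seasonal_params)
  if (any(ssp$alpha >= 0)) {
    abort_bad_arg("seasonal_params must have alpha < 0 (concave annual cycle)")
  }
  if (n_psu < n_strata || n_strata < 1) {
    abort_bad_arg("need n_psu >= n_strata >= 1 (got %d PSUs, %d strata)", n_psu, n_strata)
  }
  structure(
    list(cells = cells, dose_response_params = drp, seasonal_params = ssp,
         serum_noise_sd = serum_noise_sd, n_psu = as.integer(n_psu),
         n_strata = as.integer(n_strata), seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Published cohort x gender calibration surface. Intake columns are the
# non-supplement-taker mean/sd (ug/day) with their cell size, and the
# supplement-taker totals from which the supplement dose distribution is
# derived; RTEC consumer counts come from the fortification table.
calibration_cells <- function() {
  tibble::tribble(
    ~cohort,  ~gender,  ~n_no, ~mean_no, ~sd_no, ~n_yes, ~mean_yes, ~sd_yes, ~n_rtec, ~rtec_mean_g, ~blood_sample_fraction,
    "4-10",   "male",     348,     2.03,   0.33,     66,      5.92,    2.70,     370,           31,                   0.20,
    "4-10",   "female",   336,     1.89,   1.08,     53,      7.27,   10.63,     338,           29,                   0.20,
    "11-18",  "male",     418,     2.35,   1.30,     27,      6.11,    3.31,     307,           40,                   0.35,
    "11-18",  "female",   416,     1.90,   1.21,     23,      6.04,    2.54,     291,           31,                   0.35,
    "19-64",  "male",     613,     3.13,   2.18,     97,      9.43,    8.35,     426,           42,                   0.47,
    "19-64",  "female",   769,     2.50,   1.80,    176,      7.80,    3.98,     606,           38,                   0.47,
    "65plus", "male",     146,     3.85,   2.57,     45,      8.84,    5.34,     130,           72,                   0.47,
    "65plus", "female",   160,     2.76,   1.57,     77,      9.73,    5.42,     189,           60,                   0.47
  )
}

# Published per-cohort saturating intake-status coefficients.
calibration_dose_response <- function() {
  tibble::tribble(
    ~cohort,      ~a,     ~b,    ~c,
    "4-10",    21.38,  30.77,  2.42,
    "11-18",   36.15,  17.61,  0.34,
    "19-64",   35.78,  20.26,  0.20,
    "65plus",  27.10,  55.92,  0.07
  )
}

# Published per-cell seasonal quadratic coefficients (month 1 = January).
calibration_seasonal <- function() {
  tibble::tribble(
    ~cohort,  ~gender,  ~alpha, ~beta, ~gamma,
    "4-10",   "male",    -0.76, 10.97,  22.71,
    "4-10",   "female",  -0.43,  7.80,  24.08,
    "11-18",  "male",    -0.86, 13.13,   7.49,
    "11-18",  "female",  -0.46,  6.94,  23.09,
    "19-64",  "male",    -0.65, 10.58,  10.38,
    "19-64",  "female",  -0.53,  8.35,  21.16,
    "65plus", "male",    -0.34,  5.25,  30.68,
    "65plus", "female",  -0.47,  6.87,  23.14
  )
}

# Per-cohort target marginal serum sd (combined genders).
calibration_serum_sd <- function() {
  c("4-10" = 21.83, "11-18" = 24.41, "19-64" = 24.63, "65plus" = 22.26)
}

#' The packaged default generator configuration
#'
#' Calibrated so that the synthetic population reproduces the published
#' cohort summaries of the 2008-2012 UK National Diet and Nutrition Survey
#' waves: intake means/s.d. per cohort, gender and supplement status; serum
#' 25(OH)D means and s.d. per cohort; per-cohort saturating dose-response
#' curves; per-cell seasonal quadratics; supplement prevalence and RTEC
#' consumer fractions from the published cell sizes; blood-sampling
#' fractions of roughly 20% (children), 35% (teenagers) and 47% (adults and
#' elderly). The residual serum noise s.d. is derived deterministically per
#' cohort so that the marginal serum s.d. matches the published value after
#' accounting for the variance contributed by the intake distribution
#' (through the dose-response curve) and by the seasonal cycle.
#'
#' @param seed Integer seed (mandatory).
#' @param scale Multiplier on every cell's `n_participants` (used to scale
#'   simulations up or down); fractional scales round the cell sizes.
#' @return A `generator_config`.
#' @export
#' @examples
#' cfg <- default_generator_config(seed = 1)
#' records <- generate_cohort(cfg)
default_generator_config <- function(seed, scale = 1) {
  cal <- calibration_cells()
  cells <- tibble::tibble(
    cohort = cal$cohort,
    gender = cal$gender,
    n_participants = as.integer(round((cal$n_no + cal$n_yes) * scale)),
    intake_mean_nonsupp = cal$mean_no,
    intake_sd_nonsupp = cal$sd_no,
    supplement_prevalence = cal$n_yes / (cal$n_no + cal$n_yes),
    supp_dose_mean = cal$mean_yes - cal$mean_no,
    supp_dose_sd = sqrt(pmax(cal$sd_yes^2 - cal$sd_no^2, (0.3 * (cal$mean_yes - cal$mean_no))^2)),
    rtec_consumer_fraction = cal$n_rtec / (cal$n_no + cal$n_yes),
    rtec_mean_g = cal$rtec_mean_g,
    rtec_sd_g = 0.6 * cal$rtec_mean_g,
    blood_sample_fraction = cal$blood_sample_fraction
  )
  drp <- calibration_dose_response()
  ssp <- calibration_seasonal()
  noise <- calibrate_serum_noise(cells, drp, ssp, calibration_serum_sd())
  generator_config(cells, drp, ssp, serum_noise_sd = noise,
                   n_psu = 36L, n_strata = 9L, seed = seed)
}

# Residual serum noise per cohort: subtract, from the target marginal serum
# variance, the variance contributed by intake (pushed through the
# dose-response curve over the cell-weighted lognormal intake mixture) and
# by the centered seasonal cycle (uniform months). Quantile-grid quadrature,
# fully deterministic. Floored at 4 nmol/L.
calibrate_serum_noise <- function(cells, drp, ssp, target_sd) {
  vapply(unique(cells$cohort), function(co) {
    dr <- drp[drp$cohort == co, ]
    f <- function(x) dr$a + dr$b * (1 - exp(-dr$c * x))
    sub <- cells[cells$cohort == co, ]
    w <- sub$n_participants
    if (sum(w) == 0) w <- rep(1, nrow(sub))
    w <- w / sum(w)
    # intake mixture over gender x supplement status
    comp <- list(); cw <- c()
    for (i in seq_len(nrow(sub))) {
      p <- sub$supplement_prevalence[i]
      comp <- c(comp, list(
        lnorm_pushforward_moments(sub$intake_mean_nonsupp[i], sub$intake_sd_nonsupp[i], f),
        lnorm_pushforward_moments(sub$intake_mean_nonsupp[i] + sub$supp_dose_mean[i],
                                  sqrt(sub$intake_sd_nonsupp[i]^2 + sub$supp_dose_sd[i]^2), f)))
      cw <- c(cw, w[i] * (1 - p), w[i] * p)
    }
    mns <- vapply(comp, `[[`, 0, "mean")
    vrs <- vapply(comp, `[[`, 0, "var")
    mix_mean <- sum(cw * mns)
    var_dose <- sum(cw * (vrs + mns^2)) - mix_mean^2
    # seasonal deviation variance, uniform months, gender-weighted
    sd_rows <- ssp[ssp$cohort == co, ]
    var_season <- 0
    for (i in seq_len(nrow(sd_rows))) {
      dev <- sd_rows$alpha[i] * (1:12)^2 + sd_rows$beta[i] * (1:12)
      dev <- dev - mean(dev)
      gi <- match(sd_rows$gender[i], sub$gender)
      var_season <- var_season + w[gi] * mean(dev^2)
    }
    sqrt(max(target_sd[[co]]^2 - var_dose - var_season, 16))
  }, numeric(1))
}

#' Generate a synthetic survey cohort
#'
#' Draws one participant record per configured head: supplement-taking is
#' Bernoulli at the cell prevalence; dietary intake and (for takers) the
#' supplement dose are lognormal, moment-matched to the configured mean and
#' s.d.; RTEC grams are lognormal for the configured consumer fraction and
#' zero otherwise; blood-draw months are uniform on 1..12; PSUs are
#' assigned round-robin within strata; serum 25(OH)D is present for the
#' configured blood-sample fraction and is simulated by [simulate_serum()]
#' (values are floored at 1 nmol/L, serum being positive).
#'
#' @param config A `generator_config`.
#' @return A tibble with one row per participant and columns `id`, `cohort`,
#'   `gender`, `intake_diet`, `intake_supp`, `rtec_g`, `month`, `serum`
#'   (`NA` when not sampled), `psu`, `stratum`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    recs <- purrr::pmap(config$cells, function(cohort, gender, n_participants,
                                               intake_mean_nonsupp, intake_sd_nonsupp,
                                               supplement_prevalence, supp_dose_mean,
                                               supp_dose_sd, rtec_consumer_fraction,
                                               rtec_mean_g, rtec_sd_g,
                                               blood_sample_fraction, ...) {
      n <- n_participants
      if (n == 0L) return(NULL)
      takes_supp <- stats::rbinom(n, 1L, supplement_prevalence) == 1L
      intake_diet <- rlnorm_matched(n, intake_mean_nonsupp, intake_sd_nonsupp)
      intake_supp <- numeric(n)
      intake_supp[takes_supp] <- rlnorm_matched(sum(takes_supp), supp_dose_mean, supp_dose_sd)
      eats_rtec <- stats::rbinom(n, 1L, rtec_consumer_fraction) == 1L
      rtec_g <- numeric(n)
      rtec_g[eats_rtec] <- rlnorm_matched(sum(eats_rtec), rtec_mean_g, rtec_sd_g)
      month <- sample.int(12L, n, replace = TRUE)
      has_serum <- stats::rbinom(n, 1L, blood_sample_fraction) == 1L
      serum <- rep(NA_real_, n)
      if (any(has_serum)) {
        serum[has_serum] <- simulate_serum(
          intake_total = intake_diet[has_serum] + intake_supp[has_serum],
          month = month[has_serum], cohort = cohort, config = config,
          gender = gender)
      }
      tibble::tibble(cohort = cohort, gender = gender,
                     intake_diet = intake_diet, intake_supp = intake_supp,
                     rtec_g = rtec_g, month = month, serum = serum)
    })
    out <- dplyr::bind_rows(recs)
    n_tot <- nrow(out)
    if (n_tot == 0L) {
      return(tibble::tibble(id = integer(0), cohort = character(0), gender = character(0),
                            intake_diet = numeric(0), intake_supp = numeric(0),
                            rtec_g = numeric(0), month = integer(0), serum = numeric(0),
                            psu = integer(0), stratum = integer(0)))
    }
    psu <- ((seq_len(n_tot) - 1L) %% config$n_psu) + 1L
    stratum <- ((psu - 1L) %% config$n_strata) + 1L
    dplyr::bind_cols(tibble::tibble(id = seq_len(n_tot)), out,
                     tibble::tibble(psu = psu, stratum = stratum))
  })
}

#' Simulate serum 25(OH)D for given total intake and month
#'
#' The serum model is additive: the cohort dose-response value at the total
#' (diet + supplement) intake, plus the mean-centered seasonal deviation for
#' the blood-draw month, plus Gaussian noise with the cohort's residual
#' s.d. Because the seasonal component is centered over months 1..12, the
#' annual mean of simulated serum at fixed intake equals the dose-response
#' value exactly. Results are floored at 1 nmol/L.
#'
#' @param intake_total Total daily vitamin D intake, \eqn{\mu}g/day.
#' @param month Blood-draw month(s), integer 1-12.
#' @param cohort Cohort label, matched against the config.
#' @param config A `generator_config`.
#' @param gender Optional gender label selecting the seasonal cell; when
#'   omitted or absent from the config the cohort's cells are averaged.
#' @param noise_sd Override the configured residual noise s.d. (e.g. 0 for
#'   deterministic evaluation).
#' @return Simulated serum 25(OH)D, nmol/L.
#' @export
simulate_serum <- function(intake_total, month, cohort, config,
                           gender = NULL, noise_sd = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (any(intake_total < 0)) abort_bad_arg("intake_total must be nonnegative")
  if (any(!(month %in% 1:12))) abort_bad_arg("month must be an integer in 1..12")
  dr <- config$dose_response_params[config$dose_response_params$cohort == cohort, ]
  if (nrow(dr) != 1L) abort_bad_arg("no dose-response parameters configured for cohort '%s'", cohort)
  fit <- dose_response(dr$a, dr$b, dr$c)
  ssp <- config$seasonal_params[config$seasonal_params$cohort == cohort, ]
  if (!is.null(gender) && any(ssp$gender == gender)) ssp <- ssp[ssp$gender == gender, ]
  if (nrow(ssp) == 0L) abort_bad_arg("no seasonal parameters configured for cohort '%s'", cohort)
  dev <- rep(0, length(month))
  for (i in seq_len(nrow(ssp))) {
    sf <- seasonal_fit(ssp$alpha[i], ssp$beta[i], ssp$gamma[i])
    dev <- dev + seasonal_deviation(sf, month) / nrow(ssp)
  }
  sd_use <- noise_sd %||% unname(config$serum_noise_sd[[cohort]])
  n <- max(length(intake_total), length(month))
  noise <- if (sd_use > 0) stats::rnorm(n, 0, sd_use) else 0
  pmax(predict_serum(fit, intake_total) + dev + noise, 1)
}

#' Summarize a cohort the way survey reports print it
#'
#' Two tables: intake of vitamin D per cohort, gender and supplement status
#' (mean, SE, s.d., n of total intake, diet plus supplements), and serum
#' 25(OH)D per cohort with genders combined (mean, SE, s.d., n, and the
#' percentage of people strictly below 25 and 50 nmol/L and strictly above
#' 75 and 100 nmol/L; ties at a threshold count in neither tail).
#'
#' @param records A participant tibble as from [generate_cohort()].
#' @return A list of class `cohort_summary` with tibbles `intake` and
#'   `serum`.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) == 0L) abort_bad_arg("cannot summarize an empty cohort")
  with_status <- records |>
    dplyr::mutate(supplement = ifelse(.data$intake_supp > 0, "yes", "no"),
                  intake_total = .data$intake_diet + .data$intake_supp)
  summarise_intake <- function(d) {
    d |>
      dplyr::group_by(.data$cohort, .data$gender, .data$supplement) |>
      dplyr::summarise(mean = mean(.data$intake_total),
                       se = stats::sd(.data$intake_total) / sqrt(dplyr::n()),
                       sd = stats::sd(.data$intake_total),
                       n = dplyr::n(), .groups = "drop")
  }
  intake_tbl <- dplyr::bind_rows(
    summarise_intake(with_status),
    summarise_intake(dplyr::mutate(with_status, supplement = "total"))
  ) |>
    dplyr::arrange(.data$cohort, .data$gender, .data$supplement)
  serum_tbl <- records |>
    dplyr::filter(!is.na(.data$serum)) |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(mean = mean(.data$serum),
                     se = stats::sd(.data$serum) / sqrt(dplyr::n()),
                     sd = stats::sd(.data$serum),
                     n = dplyr::n(),
                     pct_below_25 = 100 * mean(.data$serum < 25),
                     pct_below_50 = 100 * mean(.data$serum < 50),
                     pct_above_75 = 100 * mean(.data$serum > 75),
                     pct_above_100 = 100 * mean(.data$serum > 100),
                     .groups = "drop")
  structure(list(intake = intake_tbl, serum = serum_tbl), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Intake of vitamin D (ug/day) by cohort, gender and supplement status:\n")
  print(x$intake, n = Inf)
  cat("\nSerum 25(OH)D (nmol/L) by cohort, genders combined:\n")
  print(x$serum, n = Inf)
  invisible(x)
}
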