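#' Define a cereal-fortification scenario
#'
#' @param level Vitamin D added per 100 g of ready-to-eat cereal (RTEC),
#'   \eqn{\mu}g/100 g. The baseline scenario uses 4.2 (a 30 g portion
#'   supplying 25% of the 5 \eqn{\mu}g labelling RDA); the per-serving
#'   variant (2.5 \eqn{\mu}g per 30 g serving) corresponds to 8.33.
#' @param consumers_only If `TRUE` (default), restrict the counterfactual
#'   to RTEC consumers (`rtec_g > 0`).
#' @param thresholds_below,thresholds_above Serum thresholds (nmol/L) to
#'   report prevalences strictly below / strictly above; ascending.
#' @return An object of class `fortification_scenario`.
#' @export
fortification_scenario <- function(level = 4.2, consumers_only = TRUE,
                                   thresholds_below = c(25, 50),
                                   thresholds_above = c(75, 100)) {
  if (level < 0) abort_bad_arg("fortification level must be nonnegative")
  for (th in list(thresholds_below, thresholds_above)) {
    if (length(th) && (any(th <= 0) || is.unsorted(th, strictly = TRUE))) {
      abort_bad_arg("thresholds must be strictly positive and strictly ascending")
    }
  }
  structure(list(level = level, consumers_only = isTRUE(consumers_only),
                 thresholds_below = thresholds_below,
                 thresholds_above = thresholds_above),
            class = "fortification_scenario")
}

#' Derive a fortification level from a breakfast-share rationale
#'
#' A breakfast is assumed to supply a fixed fraction of the daily labelling
#' RDA; spreading that amount over a reference dry-weight portion gives the
#' level per 100 g: `fraction x RDA / portion x 100`.
#'
#' @param labelling_rda Daily labelling RDA of vitamin D, \eqn{\mu}g/day.
#' @param breakfast_fraction Fraction of the RDA a breakfast should supply.
#' @param portion_g Reference portion, g (dry weight).
#' @param digits Decimals for reporting (round-half-up); `NULL` for full
#'   precision.
#' @return Fortification level, \eqn{\mu}g per 100 g.
#' @export
#' @examples
#' derive_fortification_level(5, 0.25, 30)  # 4.2
derive_fortification_level <- function(labelling_rda, breakfast_fraction,
                                       portion_g, digits = 1) {
  if (breakfast_fraction == 0) return(0)
  if (labelling_rda <= 0 || breakfast_fraction < 0 || portion_g <= 0) {
    abort_bad_arg("labelling_rda and portion_g must be positive, breakfast_fraction nonnegative")
  }
  lvl <- breakfast_fraction * labelling_rda / portion_g * 100
  if (is.null(digits)) lvl else round_half_up(lvl, digits)
}

#' Daily vitamin D dose contributed by fortified cereal
#'
#' @param rtec_g Daily RTEC consumption, g/day.
#' @param level Fortification level, \eqn{\mu}g/100 g.
#' @return Extra vitamin D intake, \eqn{\mu}g/day (`rtec_g x level / 100`).
#' @export
fortification_dose <- function(rtec_g, level) {
  if (any(rtec_g < 0) || any(level < 0)) abort_bad_arg("rtec_g and level must be nonnegative")
  rtec_g * level / 100
}

#' RTEC portion needed to lift intake to a target
#'
#' @param baseline_intake Current daily vitamin D intake, \eqn{\mu}g/day.
#' @param target_intake Target daily intake, \eqn{\mu}g/day.
#' @param level Fortification level, \eqn{\mu}g/100 g (> 0 unless the
#'   target is already met).
#' @return Required portion, g/day: `max(0, target - baseline) / level x
#'   100`; 0 when the baseline already meets the target.
#' @export
#' @examples
#' portion_to_reach_intake(2.48, 5, 4.2)  # ~60 g
portion_to_reach_intake <- function(baseline_intake, target_intake, level) {
  gap <- pmax(0, target_intake - baseline_intake)
  if (level <= 0) {
    if (any(gap > 0)) abort_bad_arg("target exceeds baseline but fortification level is 0: unreachable")
    return(gap)
  }
  gap / level * 100
}

#' Prevalence of serum values beyond the scenario thresholds
#'
#' "Below" and "above" are strict; ties at a threshold count in neither
#' tail.
#'
#' @param serums Numeric vector of serum 25(OH)D values, nmol/L (nonempty).
#' @param scenario A `fortification_scenario` supplying the thresholds.
#' @param digits Decimals for the percentages (round-half-up); `NULL` for
#'   full precision.
#' @return A tibble with `direction` (`"below"`/`"above"`), `threshold`
#'   (nmol/L) and `percent`.
#' @export
threshold_prevalence <- function(serums, scenario = fortification_scenario(),
                                 digits = 1) {
  serums <- serums[!is.na(serums)]
  if (length(serums) == 0L) abort_bad_arg("no serum values to tabulate")
  rows <- dplyr::bind_rows(
    tibble::tibble(direction = "below", threshold = scenario$thresholds_below,
                   percent = vapply(scenario$thresholds_below,
                                    function(t) 100 * mean(serums < t), 0)),
    tibble::tibble(direction = "above", threshold = scenario$thresholds_above,
                   percent = vapply(scenario$thresholds_above,
                                    function(t) 100 * mean(serums > t), 0))
  )
  if (!is.null(digits)) rows$percent <- round_half_up(rows$percent, digits)
  rows
}

#' Run the fortification counterfactual on a participant table
#'
#' For each participant the "without" serum is the cohort dose-response
#' value at their total (diet + supplement) intake plus the mean-centered
#' seasonal deviation for their blood-draw month; the "with" serum adds the
#' fortification dose from their recorded RTEC grams to the intake and
#' applies the *same* seasonal deviation (UV exposure held constant). The
#' month therefore cancels from every with-minus-without difference. Both
#' arms are model-based: measured serum is not needed and fortification is
#' assumed not to change anyone's RTEC consumption.
#'
#' @param records Participant tibble (columns `cohort`, `gender`,
#'   `intake_diet`, `intake_supp`, `rtec_g`, `month`).
#' @param scenario A `fortification_scenario`.
#' @param fits Named list of `dose_response_fit` objects, one per cohort
#'   present in `records`.
#' @param seasonal_fits Optional named list of polynomial `seasonal_fit`
#'   objects keyed by `"<cohort>.<gender>"` or `"<cohort>"`; participants
#'   without a matching fit get zero seasonal deviation.
#' @return An object of class `fortification_result`: a list with
#'   `participants` (per-person serum with/without and difference),
#'   `summary` (per cohort x gender mean/SE/s.d./n of each arm and of the
#'   difference), `prevalence` (threshold table per cohort for both arms),
#'   and the `scenario`.
#' @export
apply_scenario <- function(records, scenario, fits, seasonal_fits = NULL) {
  stopifnot(inherits(scenario, "fortification_scenario"))
  d <- tibble::as_tibble(records)
  if (scenario$consumers_only) d <- dplyr::filter(d, .data$rtec_g > 0)
  if (nrow(d) == 0L) abort_bad_arg("no participants left after the RTEC-consumer filter")
  missing_fit <- setdiff(unique(d$cohort), names(fits))
  if (length(missing_fit)) {
    abort_bad_arg("no dose-response fit supplied for cohort(s): %s",
                  paste(missing_fit, collapse = ", "))
  }
  season_dev <- function(cohort, gender, month) {
    key <- paste(cohort, gender, sep = ".")
    sf <- seasonal_fits[[key]] %||% seasonal_fits[[cohort]]
    if (is.null(sf)) 0 else seasonal_deviation(sf, month)
  }
  d <- d |>
    dplyr::mutate(intake_total = .data$intake_diet + .data$intake_supp,
                  extra = fortification_dose(.data$rtec_g, scenario$level)) |>
    dplyr::group_by(.data$cohort, .data$gender) |>
    dplyr::mutate(
      dev = season_dev(dplyr::first(.data$cohort), dplyr::first(.data$gender), .data$month),
      serum_without = predict_serum(fits[[dplyr::first(.data$cohort)]], .data$intake_total) + .data$dev,
      serum_with = predict_serum(fits[[dplyr::first(.data$cohort)]], .data$intake_total + .data$extra) + .data$dev,
      difference = .data$serum_with - .data$serum_without
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"dev", -"extra")
  summary_tbl <- d |>
    dplyr::group_by(.data$cohort, .data$gender) |>
    dplyr::summarise(
      dplyr::across(c("serum_with", "serum_without", "difference"),
                    list(mean = mean,
                         se = ~ stats::sd(.x) / sqrt(dplyr::n()),
                         sd = stats::sd)),
      n = dplyr::n(), .groups = "drop")
  prev_tbl <- d |>
    dplyr::select("cohort", "serum_with", "serum_without") |>
    tidyr::pivot_longer(c("serum_with", "serum_without"),
                        names_to = "arm", values_to = "serum",
                        names_prefix = "serum_") |>
    dplyr::group_by(.data$cohort, .data$arm) |>
    dplyr::reframe(threshold_prevalence(.data$serum, scenario))
  structure(list(participants = d, summary = summary_tbl,
                 prevalence = prev_tbl, scenario = scenario),
            class = "fortification_result")
}

#' @export
print.fortification_result <- function(x, ...) {
  cat(sprintf("Fortification counterfactual at %.2f ug/100 g (%s):\n",
              x$scenario$level,
              if (x$scenario$consumers_only) "RTEC consumers only" else "all participants"))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Per-participant tidy view of a fortification counterfactual
#'
#' @param x A `fortification_result`.
#' @param ... Unused.
#' @return The per-participant tibble (`serum_without`, `serum_with`,
#'   `difference`, plus identifying columns).
#' @export
tidy.fortification_result <- function(x, ...) x$participants

#' One-row-per-cell summary of a fortification counterfactual
#'
#' @inheritParams tidy.fortification_result
#' @return The cohort x gender summary tibble.
#' @export
glance.fortification_result <- function(x, ...) x$summary

#' Plot serum gains from a fortification counterfactual
#'
#' @param object A `fortification_result`.
#' @param ... Unused.
#' @return A ggplot: distribution of per-person serum gain by cohort and
#'   gender.
#' @export
autoplot.fortification_result <- function(object, ...) {
  ggplot2::ggplot(object$participants,
                  ggplot2::aes(.data$cohort, .data$difference, fill = .data$gender)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2) +
    ggplot2::labs(x = NULL, y = "Serum 25(OH)D gain (nmol/L)",
                  title = sprintf("Fortification at %.1f µg/100 g RTEC", object$scenario$level)) +
    ggplot2::theme_minimal()
}
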