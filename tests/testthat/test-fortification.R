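test_that("fortification level follows the breakfast-share derivation", {
  expect_equal(derive_fortification_level(5, 0.25, 30), 4.2)
  expect_equal(derive_fortification_level(5, 0.25, 30, digits = NULL),
               1.25 / 30 * 100, tolerance = 1e-12)
  expect_equal(derive_fortification_level(10, 0, 30), 0)
  # the 2.5 ug-per-30 g-serving variant is 8.3 per 100 g
  expect_equal(derive_fortification_level(10, 0.25, 30), 8.3)
  expect_error(derive_fortification_level(-5, 0.25, 30), "positive")
  expect_error(derive_fortification_level(5, 0.25, 0), "positive")
})

test_that("cereal dose is proportional to grams and level", {
  expect_equal(fortification_dose(30, 4.2), 1.26)
  expect_equal(fortification_dose(0, 4.2), 0)
  expect_equal(fortification_dose(100, 4.2), 4.2)
  expect_error(fortification_dose(-1, 4.2), "nonnegative")
})

test_that("portion to reach an intake target inverts the dose formula", {
  expect_equal(portion_to_reach_intake(2.48, 5, 4.2), 60)
  expect_equal(portion_to_reach_intake(6, 5, 4.2), 0)    # already met
  # doubling the level halves the portion exactly
  expect_equal(portion_to_reach_intake(2.48, 5, 8.4),
               portion_to_reach_intake(2.48, 5, 4.2) / 2)
  expect_error(portion_to_reach_intake(2, 5, 0), "unreachable")
  expect_equal(portion_to_reach_intake(6, 5, 0), 0)
})

test_that("threshold prevalences are strict and enumerable", {
  sc <- fortification_scenario(thresholds_below = 50, thresholds_above = 75)
  all60 <- threshold_prevalence(rep(60, 10), sc)
  expect_equal(all60$percent, c(0, 0))
  quart <- threshold_prevalence(c(20, 40, 60, 80), sc)
  expect_equal(quart$percent[quart$direction == "below"], 50)
  expect_equal(quart$percent[quart$direction == "above"], 25)
  # ties at the threshold count in neither tail
  tied <- threshold_prevalence(c(50, 50, 75, 100), sc)
  expect_equal(tied$percent, c(0, 25))
  expect_error(threshold_prevalence(numeric(0), sc), "no serum")
  expect_error(fortification_scenario(thresholds_below = c(50, 25)), "ascending")
  expect_error(fortification_scenario(level = -1), "nonnegative")
})

test_that("single-participant counterfactual matches the closed form", {
  # elderly male: intake 5.02, 65 g/day RTEC at 4.2 ug/100 g
  rec <- tibble::tibble(id = 1L, cohort = "65plus", gender = "male",
                        intake_diet = 5.02, intake_supp = 0, rtec_g = 65,
                        month = 6L, serum = NA_real_, psu = 1L, stratum = 1L)
  fits <- reference_dose_response()
  res <- apply_scenario(rec, fortification_scenario(level = 4.2), fits)
  want <- 55.92 * (exp(-0.07 * 5.02) - exp(-0.07 * (5.02 + 65 * 4.2 / 100)))
  expect_equal(res$participants$difference, want, tolerance = 1e-12)
  expect_equal(res$participants$serum_without,
               predict_serum(fits[["65plus"]], 5.02), tolerance = 1e-12)
})

test_that("the counterfactual is null at level zero and month-invariant", {
  rec <- generate_cohort(default_generator_config(seed = 5, scale = 0.2))
  fits <- reference_dose_response()
  seas <- setNames(
    lapply(seq_len(nrow(reference_seasonal_rows())), function(i) {
      r <- reference_seasonal_rows()[i, ]
      seasonal_fit(r$alpha, r$beta, r$gamma)
    }),
    paste(reference_seasonal_rows()$cohort, reference_seasonal_rows()$gender, sep = "."))
  null <- apply_scenario(rec, fortification_scenario(level = 0), fits, seas)
  expect_identical(null$participants$serum_with, null$participants$serum_without)
  expect_true(all(null$participants$difference == 0))
  # differences are >= 0 and independent of the blood-draw month
  res <- apply_scenario(rec, fortification_scenario(level = 4.2), fits, seas)
  expect_true(all(res$participants$difference >= 0))
  shifted <- dplyr::mutate(rec, month = (month %% 12L) + 1L)
  res2 <- apply_scenario(shifted, fortification_scenario(level = 4.2), fits, seas)
  expect_equal(res$participants$difference, res2$participants$difference,
               tolerance = 1e-12)
  # but the month does move the serum levels themselves
  expect_false(isTRUE(all.equal(res$participants$serum_without,
                                res2$participants$serum_without)))
})

test_that("gains grow with cereal consumption and saturate at the plateau", {
  fits <- reference_dose_response()
  rec <- tibble::tibble(id = 1:6, cohort = "19-64", gender = "male",
                        intake_diet = 3, intake_supp = 0,
                        rtec_g = c(10, 20, 40, 80, 160, 320),
                        month = 6L, serum = NA_real_, psu = 1L, stratum = 1L)
  res <- apply_scenario(rec, fortification_scenario(level = 4.2), fits)
  expect_true(all(diff(res$participants$difference) > 0))
  # saturation: the gain never exceeds plateau - serum_without
  headroom <- plateau(fits[["19-64"]]) - res$participants$serum_without
  expect_true(all(res$participants$difference < headroom))
  big <- apply_scenario(rec, fortification_scenario(level = 1e7), fits)
  expect_equal(big$participants$serum_with,
               rep(plateau(fits[["19-64"]]), 6), tolerance = 1e-6)
})

test_that("consumer filtering and missing fits are enforced", {
  rec <- tibble::tibble(id = 1:2, cohort = "4-10", gender = "male",
                        intake_diet = 2, intake_supp = 0, rtec_g = c(0, 30),
                        month = 3L, serum = NA_real_, psu = 1L, stratum = 1L)
  fits <- reference_dose_response()
  res <- apply_scenario(rec, fortification_scenario(), fits)
  expect_identical(nrow(res$participants), 1L)   # non-consumer excluded
  all_in <- apply_scenario(rec, fortification_scenario(consumers_only = FALSE), fits)
  expect_identical(nrow(all_in$participants), 2L)
  expect_equal(all_in$participants$difference[all_in$participants$rtec_g == 0], 0)
  expect_error(apply_scenario(dplyr::mutate(rec, rtec_g = 0),
                              fortification_scenario(), fits), "no participants")
  expect_error(apply_scenario(rec, fortification_scenario(), fits["19-64"]),
               "no dose-response fit")
})

test_that("synthetic defaults reproduce the published cohort ordering of gains", {
  rep <- run_pipeline(default_generator_config(seed = 4, scale = 0.5),
                      fortification_scenario(level = 4.2))
  gains <- rep$fortification$summary |>
    dplyr::group_by(cohort) |>
    dplyr::summarise(gain = sum(difference_mean * n) / sum(n))
  g <- setNames(gains$gain, gains$cohort)
  expect_lt(g[["4-10"]], min(g[c("11-18", "19-64", "65plus")]))
  expect_gt(g[["65plus"]], max(g[c("4-10", "11-18", "19-64")]))
  # fortified exceedance prevalence never decreases
  prev <- tidyr::pivot_wider(rep$fortification$prevalence,
                             names_from = "arm", values_from = "percent")
  above <- dplyr::filter(prev, direction == "above")
  expect_true(all(above$with >= above$without))
})
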