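test_that("generation is bit-identical under the same config and seed", {
  cfg <- tiny_config(seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # a different seed moves the draws
  cfg2 <- tiny_config(seed = 100)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("degenerate and boundary configurations behave as specified", {
  empty <- tiny_config(n = 0L)
  rec <- generate_cohort(empty)
  expect_identical(nrow(rec), 0L)
  expect_true(all(c("id", "cohort", "gender", "intake_diet", "intake_supp",
                    "rtec_g", "month", "serum", "psu", "stratum") %in% names(rec)))
  all_supp <- generate_cohort(tiny_config(supplement_prevalence = 1))
  expect_true(all(all_supp$intake_supp > 0))
  none_supp <- generate_cohort(tiny_config(supplement_prevalence = 0))
  expect_true(all(none_supp$intake_supp == 0))
})

test_that("invalid configurations are rejected naming the offence", {
  cells <- tiny_config()$cells
  bad <- cells; bad$supplement_prevalence <- c(1.2, 0.5)
  expect_error(generator_config(bad, tiny_config()$dose_response_params,
                                tiny_config()$seasonal_params,
                                c("4-10" = 15), seed = 1),
               "4-10 male.*fractions")
  bad2 <- cells; bad2$intake_mean_nonsupp[2] <- -1
  expect_error(generator_config(bad2, tiny_config()$dose_response_params,
                                tiny_config()$seasonal_params,
                                c("4-10" = 15), seed = 1),
               "4-10 female.*nonnegative")
  expect_error(generator_config(cells, tibble::tibble(cohort = "4-10", a = 20, b = -1, c = 1),
                                tiny_config()$seasonal_params, c("4-10" = 15), seed = 1),
               "b > 0")
  expect_error(generator_config(cells, tiny_config()$dose_response_params,
                                tibble::tibble(cohort = "4-10", gender = "male",
                                               alpha = 0.1, beta = 1, gamma = 1),
                                c("4-10" = 15), seed = 1),
               "alpha < 0")
  expect_error(tiny_config(seed = NULL), "seed")
})

test_that("lognormal draws are moment-matched to the configured targets", {
  withr::with_seed(5, {
    for (ms in list(c(2.03, 0.33), c(7.27, 10.63), c(31, 18.6))) {
      x <- vitdfort:::rlnorm_matched(10000L, ms[1], ms[2])
      expect_true(all(x > 0))
      expect_lt(abs(mean(x) / ms[1] - 1), 0.02 + 0.03 * (ms[2] > ms[1]))
      expect_lt(abs(sd(x) / ms[2] - 1), 0.05 + 0.10 * (ms[2] > ms[1]))
    }
    # the well-behaved cell meets the 2% bound outright
    x <- vitdfort:::rlnorm_matched(10000L, 2.03, 0.33)
    expect_lt(abs(mean(x) / 2.03 - 1), 0.02)
    expect_lt(abs(sd(x) / 0.33 - 1), 0.02)
  })
})

test_that("serum composition is additive, centered, and noise-free when asked", {
  cfg <- tiny_config()
  dr <- dose_response(21.38, 30.77, 2.42)
  # at fixed intake, the 12-month average of noiseless serum equals the
  # dose-response value exactly (centering of the seasonal deviation)
  for (intake in c(0.5, 2.6, 8)) {
    sims <- simulate_serum(rep(intake, 12), 1:12, "4-10", cfg,
                           gender = "male", noise_sd = 0)
    expect_equal(mean(sims), predict_serum(dr, intake), tolerance = 1e-12)
  }
  # direct evaluation at 2.6 ug/day: 21.38 + 30.77(1 - exp(-2.42 * 2.6))
  sims <- simulate_serum(rep(2.6, 12), 1:12, "4-10", cfg, gender = "male", noise_sd = 0)
  expect_equal(mean(sims), 21.38 + 30.77 * (1 - exp(-2.42 * 2.6)), tolerance = 1e-12)
  # a month at which the centered deviation vanishes reproduces the curve
  sf <- seasonal_fit(-0.76, 10.97, 22.71)
  devs <- seasonal_deviation(sf, 1:12)
  m0 <- which.min(abs(devs))
  expect_equal(simulate_serum(2.6, m0, "4-10", cfg, gender = "male", noise_sd = 0),
               predict_serum(dr, 2.6) + devs[m0], tolerance = 1e-12)
  expect_error(simulate_serum(1, 1, "19-64", cfg), "no dose-response")
  expect_error(simulate_serum(-1, 1, "4-10", cfg), "nonnegative")
  expect_error(simulate_serum(1, 13, "4-10", cfg), "1..12")
})

test_that("record invariants hold on a generated population", {
  rec <- generate_cohort(default_generator_config(seed = 3, scale = 0.25))
  expect_true(all(rec$intake_diet >= 0))
  expect_true(all(rec$intake_supp >= 0))
  expect_true(all(rec$rtec_g >= 0))
  expect_true(all(rec$month %in% 1:12))
  expect_true(all(is.na(rec$serum) | rec$serum > 0))
  expect_true(all(rec$psu %in% seq_len(36)))
  # each PSU sits in exactly one stratum
  expect_true(all(tapply(rec$stratum, rec$psu, function(s) length(unique(s))) == 1))
})

test_that("cohort summaries report survey-table quantities with strict thresholds", {
  one <- tibble::tibble(id = 1L, cohort = "4-10", gender = "male",
                        intake_diet = 2, intake_supp = 0, rtec_g = 30,
                        month = 6L, serum = 30, psu = 1L, stratum = 1L)
  s <- summarize_cohort(one)
  expect_equal(s$serum$pct_below_25, 0)
  expect_equal(s$serum$pct_below_50, 100)
  expect_equal(s$serum$pct_above_75, 0)
  # ties at a threshold count in neither tail
  tied <- dplyr::mutate(one[rep(1, 5), ], id = 1:5, serum = 50)
  st <- summarize_cohort(tied)
  expect_equal(st$serum$sd, 0)
  expect_equal(st$serum$pct_below_50, 0)
  expect_error(summarize_cohort(one[0, ]), "empty")
})

test_that("threshold prevalences nest on generated populations", {
  s <- summarize_cohort(generate_cohort(default_generator_config(seed = 8, scale = 0.25)))
  expect_true(all(s$serum$pct_below_25 <= s$serum$pct_below_50))
  expect_true(all(s$serum$pct_above_100 <= s$serum$pct_above_75))
})

test_that("the calibrated population matches its published summary surface", {
  rec <- generate_cohort(default_generator_config(seed = 17))
  s <- summarize_cohort(rec)
  # intake: 4-10 male non-supplement cell, target 2.03 (sd 0.33, n 348)
  cell <- dplyr::filter(s$intake, cohort == "4-10", gender == "male", supplement == "no")
  expect_lt(abs(cell$mean - 2.03), 3 * 0.33 / sqrt(cell$n))
  # serum: 4-10 combined target 51.46 (sd 21.83, n 167)
  ch <- dplyr::filter(s$serum, cohort == "4-10")
  expect_lt(abs(ch$mean - 51.46), 3 * 21.83 / sqrt(ch$n))
  # 65plus insufficiency near the published 65%
  eld <- dplyr::filter(s$serum, cohort == "65plus")
  expect_lt(abs(eld$pct_below_50 - 65), 10)
})
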