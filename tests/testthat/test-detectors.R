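test_that("sleep baseline is the mean of the first seven nights", {
  nights <- flat_sleep_week(duration = 7)
  nights$duration <- c(6, 7, 8, 7, 6, 7, 8)
  expect_equal(sleep_baseline(nights)$duration, 7.0)

  same <- flat_sleep_week()
  b <- sleep_baseline(same)
  expect_equal(b$efficiency, 93)
  expect_equal(b$deep_fraction, 20)

  expect_error(sleep_baseline(same[1:6, ]), "insufficient data")
})

test_that("insomnia needs two criteria on enough nights", {
  base <- flat_sleep_baseline()
  th <- detector_thresholds()

  expect_equal(detect_insomnia(flat_sleep_week(), base, th), 0L)

  # 4 of 7 nights far under both the duration and efficiency floors
  wk <- flat_sleep_week()
  bad <- c(1, 3, 5, 7)
  wk$duration[bad] <- 4.0
  wk$efficiency[bad] <- 70
  expect_equal(detect_insomnia(wk, base, th), 1L)

  # 3 consecutive qualifying nights also suffice
  wk2 <- flat_sleep_week()
  wk2$duration[2:4] <- 4.0
  wk2$efficiency[2:4] <- 70
  expect_equal(detect_insomnia(wk2, base, th), 1L)

  # one criterion per night never qualifies
  wk3 <- flat_sleep_week()
  wk3$duration <- 4.0
  expect_equal(detect_insomnia(wk3, base, th), 0L)

  expect_error(detect_insomnia(flat_sleep_week(), NULL, th),
               "insufficient data")
  expect_error(detect_insomnia(flat_sleep_week()[1:5, ], base, th),
               "7 nights")
})

test_that("weight percent change follows the baseline-relative formula", {
  expect_equal(weight_pct_change(80, 80), 0.0)
  expect_equal(weight_pct_change(100, 98.85), 1.15)
  expect_equal(weight_pct_change(80, 84), -5.0)
  expect_error(weight_pct_change(0, 70), "positive")

  # antisymmetry up to scale: d(a,b) = -d(b,a) * b/a
  set.seed(3)
  for (i in 1:50) {
    a <- runif(1, 50, 120)
    b <- runif(1, 50, 120)
    expect_equal(weight_pct_change(a, b),
                 -weight_pct_change(b, a) * b / a)
  }
})

test_that("cachexia thresholds rescale linearly to the monitoring horizon", {
  expect_equal(round(scaled_weight_threshold(5, 26, 6), 2), 1.15)
  expect_equal(round(scaled_weight_threshold(2, 26, 6), 1), 0.5)
  expect_equal(scaled_weight_threshold(5, 26, 26), 5.0)
  expect_error(scaled_weight_threshold(-1, 26, 6))
})

test_that("weight-loss detection uses the BMI-dependent threshold", {
  th <- detector_thresholds()
  flat <- data.frame(week = 1:6, weight = 80)
  expect_equal(detect_weight_loss(flat, 25, th), 0L)

  declining <- data.frame(week = 1:6,
                          weight = seq(100, 98.5, length.out = 6))
  expect_equal(detect_weight_loss(declining, 25, th), 1L)

  mild <- data.frame(week = 1:4, weight = c(100, 100, 99.6, 99.3))
  expect_equal(detect_weight_loss(mild, 25, th), 0L)  # 0.7% < 1.15%
  expect_equal(detect_weight_loss(mild, 19, th), 1L)  # 0.7% >= 0.5%

  expect_error(detect_weight_loss(flat[1, , drop = FALSE], 25, th),
               "insufficient data")
})

test_that("hypertension requires repeated dual exceedance by default", {
  th <- detector_thresholds()
  normo <- data.frame(day = 1:7, systolic = 120, diastolic = 70)
  expect_equal(detect_hypertension(normo, th), 0L)

  hyper <- normo
  hyper$systolic[c(2, 4, 6)] <- 150
  hyper$diastolic[c(2, 4, 6)] <- 95
  expect_equal(detect_hypertension(hyper, th), 1L)

  # systolic-only exceedance does not count under the "both" policy...
  sys_only <- normo
  sys_only$systolic[c(2, 4, 6)] <- 150
  sys_only$diastolic[c(2, 4, 6)] <- 85
  expect_equal(detect_hypertension(sys_only, th), 0L)

  # ...but does under the "either" switch
  th_either <- detector_thresholds(bp = list(systolic = 140,
                                             diastolic = 90,
                                             min_exceedances = 3,
                                             logic = "either"))
  expect_equal(detect_hypertension(sys_only, th_either), 1L)

  expect_error(detect_hypertension(normo[0, ], th), "insufficient data")
})

test_that("pyrexia fires on absolute fever or a sustained rise", {
  th <- detector_thresholds()

  expect_equal(detect_pyrexia(temp_series(36.8), th), 0L)

  # 90 minutes at 38.0 C: persistent absolute exceedance
  fever <- temp_series(36.8, override_night = 3,
                       override_samples = 10:19, override_temp = 38.0)
  expect_equal(detect_pyrexia(fever, th), 1L)

  # 3 h at 0.5 C above a 37.0 C baseline, peak 37.5 C < 37.8 C
  rise <- temp_series(37.0, override_night = 4,
                      override_samples = 10:28, override_temp = 37.5)
  expect_equal(detect_pyrexia(rise, th), 1L)

  # a single-sample spike is rejected by the persistence guard
  spike <- temp_series(36.8, override_night = 3,
                       override_samples = 10, override_temp = 38.5)
  expect_equal(detect_pyrexia(spike, th), 0L)

  shuffled <- temp_series(36.8)[c(2, 1, 3:343), ]
  expect_error(detect_pyrexia(shuffled, th), "time-ordered")
})

test_that("survey flags are the weekly OR of daily reports", {
  empty <- data.frame(day = 1:7)
  for (s in survey_symptoms()) empty[[s]] <- FALSE

  expect_equal(sum(surveys_to_flags(empty)), 0L)

  one <- empty
  one$nausea[4] <- TRUE
  flags <- surveys_to_flags(one)
  expect_equal(flags[["nausea"]], 1L)
  expect_equal(sum(flags), 1L)

  # idempotent under duplicated days
  expect_equal(surveys_to_flags(rbind(one, one)), flags)

  expect_error(surveys_to_flags(empty[0, ]), "insufficient data")
})
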