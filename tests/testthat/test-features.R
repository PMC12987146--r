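test_that("symptom counts and cumulative load agree", {
  expect_equal(weekly_symptom_count(zero_week()), 0L)
  expect_equal(weekly_symptom_count(zero_week() + 1L), 11L)
  expect_equal(weekly_symptom_count(week_with("nausea", "fatigue")), 2L)

  expect_equal(cumulative_symptom_load(NULL), 0L)
  h <- rbind(week_with("nausea", "fatigue"), zero_week(),
             week_with("nausea", "vomiting", "diarrhea", "cephalea"))
  expect_equal(cumulative_symptom_load(h[1, , drop = FALSE]), 2L)
  expect_equal(cumulative_symptom_load(h), 6L)
})

test_that("symptom duration is the run length ending now", {
  h3 <- rbind(week_with("fatigue"), week_with("fatigue"),
              week_with("fatigue"))
  expect_equal(symptom_duration("fatigue", h3), 3L)
  gap <- rbind(week_with("fatigue"), zero_week(), week_with("fatigue"))
  expect_equal(symptom_duration("fatigue", gap), 1L)
  off <- rbind(week_with("fatigue"), week_with("fatigue"), zero_week())
  expect_equal(symptom_duration("fatigue", off), 0L)
  expect_error(symptom_duration("chills", h3), "unknown symptom")
})

test_that("interaction flags are the AND of their clusters", {
  expect_equal(
    unname(interaction_flags(week_with("nausea", "vomiting"))["ix_digestive"]),
    0L)
  f <- interaction_flags(week_with("nausea", "vomiting", "diarrhea"))
  expect_equal(unname(f["ix_digestive"]), 1L)
  f2 <- interaction_flags(week_with("fatigue", "weight_loss"))
  expect_equal(unname(f2["ix_systemic"]), 1L)
  f3 <- interaction_flags(week_with("cephalea", "hypertension"))
  expect_equal(unname(f3["ix_neurological"]), 1L)
})

test_that("the assembled matrix has the 30-column manifest", {
  expect_length(feature_manifest(), 30)

  sim <- simulate_cohort(sim_config(n_patients = 25, n_weeks = 6,
                                    seed = 8))
  fm <- build_feature_matrix(sim$cohort)
  expect_equal(nrow(fm), 150)
  expect_equal(setdiff(names(fm), c("patient_id", "week")),
               feature_manifest())

  dup <- rbind(sim$cohort, sim$cohort[1, ])
  expect_error(build_feature_matrix(dup), "duplicate")

  # a single patient-week: durations equal the raw flags
  one <- sim$cohort[1, ]
  fm1 <- build_feature_matrix(one)
  expect_equal(unname(unlist(fm1[paste0("duration_", symptom_names())])),
               unname(unlist(one[symptom_names()])))
})

test_that("engineered dynamics are internally consistent", {
  sim <- simulate_cohort(sim_config(n_patients = 15, n_weeks = 6,
                                    seed = 19))
  fm <- build_feature_matrix(sim$cohort)

  for (pid in unique(fm$patient_id)) {
    p <- fm[fm$patient_id == pid, ]
    p <- p[order(p$week), ]
    # weekly count = difference of consecutive cumulative loads
    expect_equal(p$weekly_symptom_count,
                 diff(c(0, p$cumulative_symptom_load)))
    expect_equal(p$prev_week_symptom_count,
                 c(0, head(p$weekly_symptom_count, -1)))
  }

  # each interaction flag is bounded by its member flags
  expect_true(all(fm$ix_digestive <= pmin(fm$nausea, fm$vomiting,
                                          fm$diarrhea)))
  expect_true(all(fm$ix_systemic <= pmin(fm$fatigue, fm$weight_loss)))
  # durations never exceed the week index and are 0 when inactive
  for (s in symptom_names()) {
    expect_true(all(fm[[paste0("duration_", s)]] <= fm$week))
    expect_true(all(fm[[paste0("duration_", s)]][fm[[s]] == 0] == 0))
  }
})
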