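test_that("susceptibility draws follow the bounded Gaussian", {
  params <- list(mean = 1.0, sd = 0.20, lower = 0.5, upper = 1.8,
                 method = "truncate")

  # degenerate distribution collapses to the mean
  expect_equal(draw_susceptibility(5, modifyList(params, list(sd = 0))),
               rep(1.0, 5))

  set.seed(11)
  x <- draw_susceptibility(1e5, params)
  expect_true(all(x >= 0.5 & x <= 1.8))

  # empirical mean against the quadrature oracle over the truncated density
  mu <- truncnorm_mean_oracle(1.0, 0.20, 0.5, 1.8)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mu), 3 * se)
  # the package's own expectation helper agrees with the oracle
  expect_equal(susceptibility_mean(params), mu, tolerance = 1e-8)

  expect_error(
    draw_susceptibility(1, list(mean = 1, sd = 0.2, lower = 2, upper = 1,
                                method = "truncate")),
    "lower < upper")

  # clipping piles point mass at the bounds, truncation does not
  set.seed(12)
  wide <- modifyList(params, list(sd = 0.5))
  xc <- draw_susceptibility(1e4, modifyList(wide, list(method = "clip")))
  expect_true(all(xc >= 0.5 & xc <= 1.8))
  expect_gt(sum(xc == 1.8), 0)
  xt <- draw_susceptibility(1e4, wide)
  expect_equal(sum(xt == 1.8), 0)
})

test_that("initial weekly probability scales and clamps", {
  expect_equal(initial_probability(0.535, 1.0, 1.0), 0.535)
  expect_equal(initial_probability(0.6, 2.0, 1.0), 1.0)
  expect_equal(initial_probability(0.0, 1.8, 1.0), 0.0)
  expect_equal(initial_probability(c(0.2, 0.5), 1.5, c(1, 0)),
               c(0.3, 0))
  expect_error(initial_probability(1.2, 1, 1))
})

test_that("within-week sampling honors degenerate probabilities", {
  p <- setNames(c(0, 0, 0), c("a", "b", "c"))
  rules <- data.frame(trigger = character(0), target = character(0),
                      boost = numeric(0))
  set.seed(1)
  expect_equal(unname(simulate_patient_week(p, rules)), c(0L, 0L, 0L))
  expect_equal(unname(simulate_patient_week(p + 1, rules)), c(1L, 1L, 1L))

  bad <- data.frame(trigger = "a", target = "zzz", boost = 0.1)
  expect_error(simulate_patient_week(p, bad), "unknown symptom")
})

test_that("a firing trigger boosts its target to min(1, p + b)", {
  p <- setNames(c(1, 0.2), c("trig", "targ"))
  rules <- data.frame(trigger = "trig", target = "targ", boost = 0.3)
  set.seed(21)
  n <- 1e4
  hits <- vapply(seq_len(n), function(i)
    simulate_patient_week(p, rules, order = c("trig", "targ"))[["targ"]],
    integer(1))
  expected <- min(1, 0.2 + 0.3)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(hits) - expected), 3 * se)
})

test_that("cohort simulation conserves shape and is seed-deterministic", {
  cfg <- sim_config(n_patients = 20, n_weeks = 6, seed = 5)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$cohort), 20 * 6)
  expect_false(anyDuplicated(sim$cohort[c("patient_id", "week")]) > 0)
  flags <- as.matrix(sim$cohort[symptom_names()])
  expect_true(all(flags %in% c(0L, 1L)))
  expect_equal(nrow(sim$profiles), 20)
  expect_true(all(sim$profiles$susceptibility >= 0.5 &
                    sim$profiles$susceptibility <= 1.8))

  expect_identical(simulate_cohort(cfg), sim)

  tiny <- simulate_cohort(sim_config(n_patients = 1, n_weeks = 1))
  expect_equal(nrow(tiny$cohort), 1)

  # growing the cohort never reshuffles earlier patients
  sim30 <- simulate_cohort(sim_config(n_patients = 30, n_weeks = 6,
                                      seed = 5))
  expect_identical(sim30$cohort[seq_len(120), ], sim$cohort)
})

test_that("with boosts off and flat modifiers, prevalence recovers p_base * E[F_sus]", {
  cfg <- sim_config(n_patients = 2000, n_weeks = 6,
                    correlation_rules = default_correlation_rules(0),
                    seed = 31)
  sim <- simulate_cohort(cfg)
  prev <- prevalence(sim$cohort) / 100
  efs <- truncnorm_mean_oracle(1.0, 0.20, 0.5, 1.8)
  expected <- pmin(default_p_base() * efs, 1)
  n <- nrow(sim$cohort)
  for (s in symptom_names()) {
    se <- sqrt(expected[s] * (1 - expected[s]) / n)
    expect_lt(abs(prev[s] - expected[s]), 3 * se)
  }
})

test_that("adding a correlation rule never decreases target prevalence", {
  base_rules <- default_correlation_rules(0)
  with_rule <- rbind(base_rules,
                     data.frame(trigger = "fatigue", target = "insomnia",
                                boost = 0.25))
  cfg0 <- sim_config(n_patients = 150, n_weeks = 6,
                     correlation_rules = base_rules, seed = 77)
  cfg1 <- sim_config(n_patients = 150, n_weeks = 6,
                     correlation_rules = with_rule, seed = 77)
  s0 <- simulate_cohort(cfg0)$cohort
  s1 <- simulate_cohort(cfg1)$cohort
  # paired seed: the boost can only flip the target 0 -> 1
  expect_true(all(s1$insomnia >= s0$insomnia))
  expect_gte(mean(s1$insomnia), mean(s0$insomnia))
})

test_that("configuration validation rejects inconsistent inputs", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(sampling_order = c("nausea", "fatigue")),
               "permutation")
  expect_error(sim_config(p_base = c(nausea = 1.2)), "\\[0, 1\\]")
  expect_error(
    sim_config(correlation_rules = data.frame(
      trigger = "nausea", target = "nausea", boost = 0.1)),
    "trigger != target")
  tm <- sim_config(temporal_modifiers = cycle_ramp_modifiers(6))
  expect_length(tm$temporal_modifiers$fatigue, 6)
})

test_that("simulation config round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_patients: 12",
    "n_weeks: 4",
    "seed: 9",
    "susceptibility: {mean: 1.0, sd: 0.1, lower: 0.7, upper: 1.5}",
    "correlation_rules:",
    "  - {trigger: nausea, target: vomiting, boost: 0.2}"
  ), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_patients, 12L)
  expect_equal(cfg$susceptibility$sd, 0.1)
  expect_equal(nrow(cfg$correlation_rules), 1)
  expect_equal(nrow(simulate_cohort(cfg)$cohort), 48)
})
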