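#' Draw patient susceptibility factors from a bounded Gaussian
#'
#' Each simulated patient receives an individual susceptibility factor
#' that scales all of their baseline symptom probabilities, representing
#' inherent propensity to develop adverse effects. Factors are drawn from
#' a Gaussian (default mean 1.0, sd 0.20) bounded to \[0.5, 1.8\].
#'
#' With `method = "truncate"` the draw follows the true truncated normal
#' (sampled by inverse-CDF, so each draw consumes exactly one uniform);
#' `method = "clip"` instead clamps unbounded normal draws to the bounds,
#' which piles point mass at the endpoints and is provided only for
#' comparison.
#'
#' @param n Number of draws.
#' @param params List with `mean`, `sd`, `lower`, `upper` and optional
#'   `method` (`"truncate"`, the default, or `"clip"`).
#' @return Numeric vector of length `n`, all values within the bounds.
#' @export
draw_susceptibility <- function(n, params = list(mean = 1.0, sd = 0.20,
                                                 lower = 0.5, upper = 1.8,
                                                 method = "truncate")) {
  params$method <- match.arg(params$method %||% "truncate",
                             c("truncate", "clip"))
  validate_susceptibility(params)
  if (params$sd == 0) return(rep(params$mean, n))
  if (params$method == "clip") {
    return(pmin(params$upper,
                pmax(params$lower, rnorm(n, params$mean, params$sd))))
  }
  plo <- pnorm(params$lower, params$mean, params$sd)
  phi <- pnorm(params$upper, params$mean, params$sd)
  qnorm(plo + runif(n) * (phi - plo), params$mean, params$sd)
}

#' Initial weekly symptom probability
#'
#' The dynamic probability that a symptom occurs for a given patient-week
#' is the baseline probability scaled by the patient's susceptibility
#' factor and the week's temporal modifier, clamped to \[0, 1\].
#'
#' @param p_base Baseline probability in \[0, 1\].
#' @param f_sus Patient susceptibility factor (> 0).
#' @param m_temp Temporal modifier (>= 0).
#' @return Probability `min(1, max(0, p_base * f_sus * m_temp))`.
#'   Vectorized over its arguments.
#' @export
initial_probability <- function(p_base, f_sus, m_temp = 1) {
  stopifnot(all(p_base >= 0 & p_base <= 1), all(f_sus > 0),
            all(m_temp >= 0))
  pmax(pmin(p_base * f_sus * m_temp, 1), 0)
}

#' Simulate one patient-week of symptom flags
#'
#' Symptoms are drawn sequentially in the configured order: for each
#' symptom a uniform variate is compared against its *current*
#' probability, and whenever a symptom occurs, every correlation rule it
#' triggers immediately boosts the current probability of the rule's
#' target (additively, clamped at 1) before that target is drawn. Boosts
#' act within the current week only; the probabilities passed in are
#' rebuilt from the baseline model each week.
#'
#' @param current_probs Named probability vector (one entry per symptom).
#' @param rules Data frame of correlation rules (`trigger`, `target`,
#'   `boost`).
#' @param order Character permutation of `names(current_probs)` giving the
#'   draw order.
#' @return Named integer 0/1 vector in the order of `current_probs`.
#' @export
simulate_patient_week <- function(current_probs,
                                  rules = default_correlation_rules(),
                                  order = names(current_probs)) {
  symptoms <- names(current_probs)
  if (is.null(symptoms))
    stop("`current_probs` must be named", call. = FALSE)
  stopifnot(all(current_probs >= 0 & current_probs <= 1))
  validate_rules(rules, symptoms)
  if (!setequal(order, symptoms) || length(order) != length(symptoms))
    stop("`order` must be a permutation of the symptom names",
         call. = FALSE)

  p <- current_probs
  x <- setNames(integer(length(symptoms)), symptoms)
  for (s in order) {
    x[[s]] <- as.integer(runif(1) < p[[s]])
    if (x[[s]] == 1L) {
      hit <- rules$trigger == s
      if (any(hit)) {
        for (i in which(hit)) {
          tg <- rules$target[i]
          p[[tg]] <- min(1, p[[tg]] + rules$boost[i])
        }
      }
    }
  }
  x[symptoms]
}

#' Simulate a longitudinal adverse-effect cohort
#'
#' Generates the complete weekly binary symptom panel for a synthetic
#' cohort: each patient gets a susceptibility factor and a baseline BMI,
#' then for every week the per-symptom probabilities are rebuilt from the
#' baseline model ([initial_probability()]) and the week is sampled with
#' within-week correlation boosts ([simulate_patient_week()]).
#'
#' Randomness is organised as one deterministic substream per patient,
#' derived arithmetically from the root seed, so growing the cohort never
#' reshuffles earlier patients.
#'
#' @param config A [sim_config()] object.
#' @return List with two data frames:
#' \describe{
#'   \item{profiles}{`patient_id`, `susceptibility`, `bmi_baseline`.}
#'   \item{cohort}{`patient_id`, `week` (1-based), one 0/1 column per
#'     symptom; exactly `n_patients * n_weeks` rows.}
#' }
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 5, n_weeks = 6, seed = 7))
#' dim(sim$cohort)
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  symptoms <- names(config$p_base)
  n <- config$n_patients
  w <- config$n_weeks

  ids <- sprintf("P%04d", seq_len(n))
  sus <- numeric(n)
  bmi <- numeric(n)
  flags <- matrix(0L, nrow = n * w, ncol = length(symptoms),
                  dimnames = list(NULL, symptoms))
  mtemp <- do.call(rbind, config$temporal_modifiers)  # symptom x week

  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i))
    sus[i] <- draw_susceptibility(1, config$susceptibility)
    bmi[i] <- runif(1, config$bmi_range[1], config$bmi_range[2])
    for (k in seq_len(w)) {
      p <- initial_probability(config$p_base, sus[i],
                               mtemp[symptoms, k])
      flags[(i - 1L) * w + k, ] <-
        simulate_patient_week(p, config$correlation_rules,
                              config$sampling_order)
    }
  }

  cohort <- data.frame(
    patient_id = rep(ids, each = w),
    week = rep(seq_len(w), times = n),
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(flags))
  profiles <- data.frame(patient_id = ids, susceptibility = sus,
                         bmi_baseline = bmi, stringsAsFactors = FALSE)
  list(profiles = profiles, cohort = cohort)
}

# Deterministic per-patient substream seed, independent of cohort size.
patient_seed <- function(root_seed, patient_index) {
  as.integer((as.numeric(root_seed) + 10007 * as.numeric(patient_index)) %%
               2147483647)
}

#' Mean of the bounded susceptibility distribution
#'
#' Expected value of the truncated-Gaussian susceptibility factor,
#' computed by numeric quadrature over the truncated density. Used to
#' predict cohort-level symptom prevalence (`p_base * E[F_sus]` when
#' boosts are off and temporal modifiers are flat).
#'
#' @param params Susceptibility parameter list as in
#'   [draw_susceptibility()].
#' @return Scalar expectation.
#' @export
susceptibility_mean <- function(params = list(mean = 1.0, sd = 0.20,
                                              lower = 0.5, upper = 1.8)) {
  validate_susceptibility(params)
  if (params$sd == 0) return(params$mean)
  z <- pnorm(params$upper, params$mean, params$sd) -
    pnorm(params$lower, params$mean, params$sd)
  f <- function(x) x * dnorm(x, params$mean, params$sd) / z
  stats::integrate(f, params$lower, params$upper)$value
}

#' Write a simulated cohort to CSV files
#'
#' Writes `cohort.csv` (schema `patient_id,week,<symptom columns>`) and
#' `profiles.csv` (`patient_id,susceptibility,bmi_baseline`) into a
#' directory.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pc <- file.path(dir, "cohort.csv")
  pp <- file.path(dir, "profiles.csv")
  write.csv(sim$cohort, pc, row.names = FALSE)
  write.csv(sim$profiles, pp, row.names = FALSE)
  invisible(c(cohort = pc, profiles = pp))
}
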