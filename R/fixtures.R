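#' Synthetic signal generators for detector testing
#'
#' These generators produce raw wearable-style streams (sleep nights,
#' blood-pressure readings, weekly weights, skin-temperature samples,
#' daily surveys) whose statistical structure matches what the clinical
#' detectors assume: quiet baselines when a condition is absent, and
#' deviations that clear the detection thresholds by a decisive margin
#' when it is present. They are test oracles, not physiological models:
#' active signals exceed the relevant threshold by a margin that scales
#' with `severity`, negatives stay well inside it, and small Gaussian
#' noise (sleep duration sd 0.25 h, BP sd 4/3 mmHg, weight sd 0.1 kg,
#' skin temperature sd 0.1 degrees C) is layered on top.
#'
#' All generators consume R's global random stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @name signal_fixtures
NULL

default_sleep_baseline <- function() {
  list(duration = 7.5, efficiency = 93, deep_fraction = 20,
       rem_fraction = 21)
}

#' Generate one week of sleep nights
#'
#' Inactive weeks fluctuate around the baseline with small noise, so at
#' most one insomnia criterion can fire per night. Active weeks contain
#' five disturbed nights on which sleep duration falls below the absolute
#' 6 h floor and efficiency below the 85% floor (both by a margin growing
#' with `severity`), and deep/REM shares drop relative to baseline —
#' decisively satisfying the two-of-three criteria rule on more than four
#' of seven nights.
#'
#' @param insomnia_active Logical flag to emulate.
#' @param baseline List of baseline statistics as returned by
#'   [sleep_baseline()].
#' @param severity Positive severity multiplier (margin scale); must be
#'   > 0 when `insomnia_active`.
#' @param thresholds A [detector_thresholds()] object (margins are placed
#'   relative to its sleep thresholds).
#' @return Data frame of 7 rows: `night`, `duration`, `efficiency`,
#'   `deep_fraction`, `rem_fraction`.
#' @export
synth_sleep_week <- function(insomnia_active,
                             baseline = default_sleep_baseline(),
                             severity = 1,
                             thresholds = detector_thresholds()) {
  stopifnot(baseline$duration > 0, baseline$efficiency > 0,
            baseline$efficiency <= 100)
  if (insomnia_active && severity <= 0)
    stop("`severity` must be > 0 for an active week", call. = FALSE)
  s <- thresholds$sleep
  m <- pmin(0.9, 0.25 * severity)  # fractional margin beyond threshold
  out <- data.frame(
    night = 1:7,
    duration = baseline$duration + rnorm(7, 0, 0.25),
    efficiency = pmin(100, baseline$efficiency + rnorm(7, 0, 1)),
    deep_fraction = baseline$deep_fraction + rnorm(7, 0, 0.8),
    rem_fraction = baseline$rem_fraction + rnorm(7, 0, 0.8)
  )
  if (insomnia_active) {
    bad <- sort(sample(7, 5))
    out$duration[bad] <- s$absolute_min_hours * (1 - m) + rnorm(5, 0, 0.25)
    out$efficiency[bad] <- s$absolute_min_efficiency * (1 - m) +
      rnorm(5, 0, 1)
    out$deep_fraction[bad] <-
      baseline$deep_fraction * (1 - s$stage_drop_frac) * (1 - m)
    out$rem_fraction[bad] <-
      baseline$rem_fraction * (1 - s$stage_drop_frac) * (1 - m)
  }
  out$duration <- pmax(out$duration, 0.5)
  out$efficiency <- pmin(100, pmax(out$efficiency, 5))
  out
}

#' Generate one week of blood-pressure readings
#'
#' Normotensive weeks read around 118/76 mmHg; hypertensive weeks contain
#' five readings centred on 156/100 mmHg — comfortably past the 140/90
#' mmHg rule on more than the required number of readings.
#'
#' @param hypertension_active Logical flag to emulate.
#' @return Data frame of 7 rows: `day`, `systolic`, `diastolic`,
#'   `heart_rate`.
#' @export
synth_bp_week <- function(hypertension_active) {
  sys <- 118 + rnorm(7, 0, 4)
  dia <- 76 + rnorm(7, 0, 3)
  if (hypertension_active) {
    hi <- sort(sample(7, 5))
    sys[hi] <- 156 + rnorm(5, 0, 4)
    dia[hi] <- 100 + rnorm(5, 0, 3)
  }
  data.frame(day = 1:7, systolic = sys, diastolic = pmin(dia, sys - 10),
             heart_rate = 70 + rnorm(7, 0, 5))
}

#' Generate a weekly weight series
#'
#' Active series lose 2.5% of baseline linearly across the horizon (past
#' the 2% construction floor and well past the 1.15% detection
#' threshold); inactive series drift uniformly within +/-0.3% of
#' baseline. Measurement noise sd is 0.1 kg.
#'
#' @param weight_loss_active Logical flag to emulate.
#' @param baseline_kg Starting weight in kg.
#' @param n_weeks Number of weekly readings.
#' @return Data frame: `week`, `weight`.
#' @export
synth_weight_series <- function(weight_loss_active, baseline_kg = 72,
                                n_weeks = 6) {
  stopifnot(baseline_kg > 0, n_weeks >= 1)
  wk <- seq_len(n_weeks)
  if (weight_loss_active && n_weeks > 1) {
    frac <- (wk - 1) / (n_weeks - 1)
    w <- baseline_kg * (1 - 0.025 * frac)
  } else {
    w <- baseline_kg * (1 + runif(n_weeks, -0.003, 0.003))
  }
  data.frame(week = wk, weight = w + rnorm(n_weeks, 0, 0.1))
}

#' Generate a week of nocturnal skin-temperature samples
#'
#' Seven nightly sessions of eight hours at 10-minute cadence around a
#' per-series baseline drawn in 36.5-37.0 degrees C. Active weeks embed,
#' on a night after the first (the detector's baseline night), either an
#' absolute fever episode (90 minutes around 38.4 degrees C) or a
#' sustained-rise episode (3.5 hours at baseline + 0.8 degrees C), the
#' mode chosen at random. Inactive weeks carry only 0.1 degrees C noise.
#'
#' @param pyrexia_active Logical flag to emulate.
#' @param cadence_minutes Sampling cadence.
#' @return Data frame: `night`, `time` (seconds from series start),
#'   `temperature`.
#' @export
synth_temp_series <- function(pyrexia_active, cadence_minutes = 10) {
  base <- runif(1, 36.5, 37.0)
  per_night <- 8 * 60 / cadence_minutes + 1
  night <- rep(1:7, each = per_night)
  within <- rep(seq_len(per_night) - 1, times = 7) * cadence_minutes * 60
  time <- (night - 1) * 24 * 3600 + within
  temperature <- base + rnorm(length(time), 0, 0.1)
  mode <- NULL
  if (pyrexia_active) {
    ep_night <- sample(3:5, 1)
    mode <- sample(c("absolute", "rise"), 1)
    start <- sample(6:20, 1)
    len <- if (mode == "absolute") 10 else 22   # 90 min / 3.5 h spans
    level <- if (mode == "absolute") 38.4 else base + 0.8
    idx <- which(night == ep_night)[start:(start + len - 1)]
    temperature[idx] <- level + rnorm(len, 0, 0.05)
  }
  out <- data.frame(night = night, time = time, temperature = temperature)
  attr(out, "episode_mode") <- mode
  out
}

#' Generate one week of daily survey responses
#'
#' Each survey-sourced symptom present in the weekly flags is reported on
#' one to four random days (at least one); absent symptoms are never
#' reported.
#'
#' @param week_flags Named 0/1 vector containing at least the
#'   [survey_symptoms()].
#' @return Data frame of 7 rows: `day` plus one logical column per survey
#'   symptom.
#' @export
synth_survey_week <- function(week_flags) {
  syms <- survey_symptoms()
  missing <- setdiff(syms, names(week_flags))
  if (length(missing))
    stop("`week_flags` lacks survey symptom(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(day = 1:7)
  for (s in syms) {
    col <- rep(FALSE, 7)
    if (week_flags[[s]] > 0) col[sample(7, sample(1:4, 1))] <- TRUE
    out[[s]] <- col
  }
  out
}
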