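#' Detector threshold configuration
#'
#' All clinical thresholds used by the rule-based detectors. Published
#' criteria often give bands rather than points (e.g. a ">20-30%"
#' sleep-duration reduction, an "80-85%" efficiency floor, "1-2%" weight
#' loss over six weeks); the defaults take the more sensitive end of each
#' band, consistent with a screening tool that favors recall.
#'
#' @param sleep List: `duration_drop_frac` (fractional drop from baseline
#'   duration), `absolute_min_hours`, `efficiency_drop_points` (percentage
#'   points below baseline efficiency), `absolute_min_efficiency`,
#'   `stage_drop_frac` (fractional drop of deep or REM share),
#'   `nights_consecutive`, `nights_of_seven`, `baseline_days`.
#' @param weight List: `loss_pct_6wk` (percent loss over the monitoring
#'   horizon; default is the 5%-over-26-weeks cachexia criterion rescaled
#'   to 6 weeks), `loss_pct_6wk_low_bmi` (rescaled 2% criterion for
#'   baseline BMI under `bmi_cutoff`), `bmi_cutoff`, `horizon_weeks`,
#'   `reference_weeks`.
#' @param bp List: `systolic` (mmHg), `diastolic` (mmHg),
#'   `min_exceedances` (readings over threshold within the week needed to
#'   flag), `logic` — `"both"` requires systolic *and* diastolic
#'   exceedance in the same reading (the published wording), `"either"`
#'   the usual clinical alternative.
#' @param temp List: `fever_abs` (degrees C), `rise_delta` (degrees C above
#'   nightly baseline), `rise_duration_hours`, `persist_minutes` (minimum
#'   contiguous minutes above `fever_abs` to count as a persistent
#'   exceedance rather than a spike).
#' @return Object of class `detector_thresholds`.
#' @export
detector_thresholds <- function(
    sleep = list(duration_drop_frac = 0.20, absolute_min_hours = 6,
                 efficiency_drop_points = 10, absolute_min_efficiency = 85,
                 stage_drop_frac = 0.15, nights_consecutive = 3,
                 nights_of_seven = 4, baseline_days = 7),
    weight = list(loss_pct_6wk = 1.15, loss_pct_6wk_low_bmi = 0.5,
                  bmi_cutoff = 20, horizon_weeks = 6,
                  reference_weeks = 26),
    bp = list(systolic = 140, diastolic = 90, min_exceedances = 3,
              logic = "both"),
    temp = list(fever_abs = 37.8, rise_delta = 0.4,
                rise_duration_hours = 2, persist_minutes = 30)) {
  bp$logic <- match.arg(bp$logic, c("both", "either"))
  th <- list(sleep = sleep, weight = weight, bp = bp, temp = temp)
  flat <- unlist(lapply(th, function(x) Filter(is.numeric, x)))
  if (any(flat <= 0)) stop("all thresholds must be positive", call. = FALSE)
  if (sleep$nights_of_seven > 7)
    stop("`nights_of_seven` cannot exceed 7", call. = FALSE)
  structure(th, class = "detector_thresholds")
}

#' Per-patient sleep baseline
#'
#' Arithmetic means of duration, efficiency and deep/REM shares over the
#' first `baseline_days` monitored nights (seven by default). All later
#' insomnia evaluations are relative to this baseline.
#'
#' @param nights Data frame with columns `duration` (hours), `efficiency`
#'   (percent), `deep_fraction`, `rem_fraction` (percent of sleep).
#' @param baseline_days Number of initial nights used.
#' @return List with `duration`, `efficiency`, `deep_fraction`,
#'   `rem_fraction`.
#' @export
sleep_baseline <- function(nights, baseline_days = 7) {
  if (nrow(nights) < baseline_days)
    stop("insufficient data: need at least ", baseline_days,
         " nights for a sleep baseline", call. = FALSE)
  b <- nights[seq_len(baseline_days), ]
  list(duration = mean(b$duration), efficiency = mean(b$efficiency),
       deep_fraction = mean(b$deep_fraction),
       rem_fraction = mean(b$rem_fraction))
}

# per-night criterion count for the insomnia rule
sleep_night_criteria <- function(nights, baseline, s) {
  c1 <- nights$duration < baseline$duration * (1 - s$duration_drop_frac) |
    nights$duration < s$absolute_min_hours
  c2 <- nights$efficiency < baseline$efficiency - s$efficiency_drop_points |
    nights$efficiency < s$absolute_min_efficiency
  # deep and/or REM reduction counts as a single fragmentation criterion
  c3 <- nights$deep_fraction <
    baseline$deep_fraction * (1 - s$stage_drop_frac) |
    nights$rem_fraction < baseline$rem_fraction * (1 - s$stage_drop_frac)
  cbind(c1, c2, c3)
}

longest_run <- function(x) {
  if (!length(x)) return(0L)
  r <- rle(as.logical(x))
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Weekly insomnia detection
#'
#' A night *qualifies* when at least two of three criteria hold: (1)
#' duration below baseline by more than the configured fraction or under
#' the absolute floor (6 h); (2) efficiency below baseline by more than
#' the configured points or under the absolute floor; (3) deep and/or REM
#' share reduced versus baseline by more than the configured fraction.
#' The week is flagged when qualifying nights occur on at least
#' `nights_consecutive` consecutive nights or at least `nights_of_seven`
#' of the seven.
#'
#' @param nights Data frame of exactly 7 nights (columns as in
#'   [sleep_baseline()]), in chronological order.
#' @param baseline Result of [sleep_baseline()].
#' @param thresholds A [detector_thresholds()] object.
#' @return Integer 0/1 flag.
#' @export
detect_insomnia <- function(nights, baseline,
                            thresholds = detector_thresholds()) {
  if (is.null(baseline))
    stop("insufficient data: missing sleep baseline", call. = FALSE)
  s <- thresholds$sleep
  if (nrow(nights) != 7)
    stop("insomnia is evaluated on exactly 7 nights", call. = FALSE)
  qual <- rowSums(sleep_night_criteria(nights, baseline, s)) >= 2
  flag <- longest_run(qual) >= s$nights_consecutive ||
    sum(qual) >= s$nights_of_seven
  as.integer(flag)
}

#' Percent weight variation from baseline
#'
#' `(baseline - current) / baseline * 100`: positive values are losses,
#' gains come out negative.
#'
#' @param baseline_kg Baseline weight (kg, > 0).
#' @param current_kg Current weight (kg).
#' @return Percent change. Vectorized over `current_kg`.
#' @export
weight_pct_change <- function(baseline_kg, current_kg) {
  if (any(baseline_kg <= 0))
    stop("baseline weight must be positive", call. = FALSE)
  (baseline_kg - current_kg) / baseline_kg * 100
}

#' Rescale a weight-loss criterion to a shorter horizon
#'
#' International cachexia criteria are stated over 6 months (>5% loss, or
#' >2% if baseline BMI < 20). For a shorter monitoring horizon the
#' criterion is rescaled linearly: 5% over 26 weeks corresponds to about
#' 1.15% over 6 weeks, and 2% to about 0.5%.
#'
#' @param reference_pct Criterion percentage over the reference period.
#' @param reference_weeks Reference period length in weeks (26 for 6
#'   months).
#' @param horizon_weeks Monitoring horizon in weeks.
#' @return Rescaled percentage.
#' @export
scaled_weight_threshold <- function(reference_pct, reference_weeks = 26,
                                    horizon_weeks = 6) {
  stopifnot(reference_pct > 0, reference_weeks > 0, horizon_weeks > 0)
  reference_pct * horizon_weeks / reference_weeks
}

#' Involuntary weight-loss detection over a weekly series
#'
#' The weight baseline is the mean of the first two weekly readings (the
#' first alone if only one precedes the evaluation). The flag raises when
#' the percent loss from baseline exceeds the active threshold at any
#' reading: the standard rescaled criterion, or the more sensitive
#' low-BMI criterion when `bmi_baseline` is under the cutoff.
#'
#' @param series Data frame with columns `week`, `weight` (kg), in week
#'   order.
#' @param bmi_baseline Baseline BMI (kg/m^2).
#' @param thresholds A [detector_thresholds()] object.
#' @return Integer 0/1 flag.
#' @export
detect_weight_loss <- function(series, bmi_baseline = 25,
                               thresholds = detector_thresholds()) {
  w <- thresholds$weight
  if (nrow(series) < 2)
    stop("insufficient data: need at least 2 weight readings",
         call. = FALSE)
  baseline <- mean(series$weight[seq_len(min(2, nrow(series)))])
  delta <- weight_pct_change(baseline, series$weight)
  thr <- if (bmi_baseline < w$bmi_cutoff) w$loss_pct_6wk_low_bmi else
    w$loss_pct_6wk
  as.integer(max(delta) >= thr)
}

#' Weekly hypertension detection
#'
#' A reading *exceeds* when systolic and diastolic pressures are both at
#' or above their thresholds (140/90 mmHg by default; `logic = "either"`
#' accepts either one). The week is flagged when at least
#' `min_exceedances` readings exceed, so a single artifactual measurement
#' cannot raise the flag.
#'
#' @param readings Data frame with columns `systolic`, `diastolic` (mmHg).
#' @param thresholds A [detector_thresholds()] object.
#' @return Integer 0/1 flag.
#' @export
detect_hypertension <- function(readings,
                                thresholds = detector_thresholds()) {
  b <- thresholds$bp
  if (nrow(readings) == 0)
    stop("insufficient data: no blood-pressure readings", call. = FALSE)
  hi_s <- readings$systolic >= b$systolic
  hi_d <- readings$diastolic >= b$diastolic
  exceed <- if (b$logic == "both") hi_s & hi_d else hi_s | hi_d
  as.integer(sum(exceed) >= b$min_exceedances)
}

#' Weekly pyrexia detection from nocturnal skin temperature
#'
#' Two routes raise the flag: (1) skin temperature persistently above the
#' absolute fever threshold (37.8 degrees C) for at least
#' `persist_minutes` of contiguous recording; (2) a sustained rise of
#' more than `rise_delta` above the patient's nightly baseline lasting
#' longer than `rise_duration_hours`. The nightly baseline is the median
#' of the first recorded night. Runs are broken at recording gaps longer
#' than 30 minutes (session boundaries).
#'
#' @param samples Data frame with columns `time` (POSIXct or numeric
#'   seconds), `temperature` (degrees C) and optionally `night` (integer
#'   session index); rows must be time-ordered.
#' @param thresholds A [detector_thresholds()] object.
#' @return Integer 0/1 flag.
#' @export
detect_pyrexia <- function(samples, thresholds = detector_thresholds()) {
  tt <- thresholds$temp
  t_sec <- as.numeric(samples$time)
  if (is.unsorted(t_sec))
    stop("temperature samples must be time-ordered", call. = FALSE)
  if (!is.null(samples$night)) {
    first <- samples$temperature[samples$night == min(samples$night)]
  } else {
    first <- samples$temperature[t_sec - t_sec[1] <= 24 * 3600]
  }
  baseline <- median(first)

  gap_break <- c(FALSE, diff(t_sec) > 30 * 60)
  span_exceeds <- function(above, min_sec, strict) {
    grp <- cumsum(gap_break | c(FALSE, diff(above) != 0))
    for (g in unique(grp[above])) {
      idx <- which(grp == g & above)
      span <- t_sec[max(idx)] - t_sec[min(idx)]
      if (if (strict) span > min_sec else span >= min_sec) return(TRUE)
    }
    FALSE
  }

  abs_hit <- span_exceeds(samples$temperature > tt$fever_abs,
                          tt$persist_minutes * 60, strict = FALSE)
  rise_hit <- span_exceeds(
    samples$temperature > baseline + tt$rise_delta,
    tt$rise_duration_hours * 3600, strict = TRUE)
  as.integer(abs_hit || rise_hit)
}

#' Weekly survey-derived symptom flags
#'
#' Nausea, vomiting, diarrhea, abdominal pain, cephalea, alopecia and
#' fatigue cannot be inferred from wearables and are taken from daily
#' self-report surveys: the weekly flag for each is the logical OR of the
#' week's daily responses.
#'
#' @param responses Data frame with one row per surveyed day and logical
#'   (or 0/1) columns for the seven survey symptoms.
#' @return Named integer 0/1 vector over the survey symptoms.
#' @export
surveys_to_flags <- function(responses) {
  if (nrow(responses) == 0)
    stop("insufficient data: no survey responses in the week",
         call. = FALSE)
  syms <- survey_symptoms()
  missing <- setdiff(syms, names(responses))
  if (length(missing))
    stop("survey responses lack column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  vapply(responses[syms], function(col) as.integer(any(col > 0)),
         integer(1))
}

#' Symptoms assessed by self-report
#' @return Character vector of the seven survey-sourced symptom names.
#' @export
survey_symptoms <- function() {
  c("nausea", "vomiting", "diarrhea", "abdominal_pain", "cephalea",
    "alopecia", "fatigue")
}
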