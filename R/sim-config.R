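#' Adverse-effect catalogue for Pembrolizumab plus chemotherapy cohorts
#'
#' The eleven adverse effects tracked by the monitoring pipeline, in the
#' canonical column order used by every tabular output of the package.
#'
#' @return Character vector of length 11.
#' @export
symptom_names <- function() {
  c("insomnia", "nausea", "vomiting", "diarrhea", "abdominal_pain",
    "cephalea", "hypertension", "pyrexia", "alopecia", "fatigue",
    "weight_loss")
}

#' Default baseline weekly occurrence probabilities
#'
#' Baseline probabilities (P_base) that each adverse effect occurs in a
#' given patient-week before susceptibility and temporal scaling, taken
#' from published prevalence figures for Pembrolizumab combined with
#' chemotherapy.
#'
#' @return Named numeric vector over [symptom_names()], values in \[0, 1\].
#' @export
default_p_base <- function() {
  c(insomnia = 0.21, nausea = 0.535, vomiting = 0.29, diarrhea = 0.43,
    abdominal_pain = 0.29, cephalea = 0.25, hypertension = 0.454,
    pyrexia = 0.24, alopecia = 0.54, fatigue = 0.585, weight_loss = 0.27)
}

#' Default trigger-target correlation rules
#'
#' Clinical dependencies between adverse effects encoded as trigger-target
#' pairs: when the trigger symptom fires in a week, the target symptom's
#' probability is additively boosted by `boost` for that same week. The
#' default set reads each symptom's documented correlates as rules pointing
#' *into* that symptom (e.g. vomiting is correlated with nausea, so nausea
#' triggers a boost on vomiting); this directional reading is an
#' interpretation, and both the rule set and the boost size are
#' configurable.
#'
#' @param boost Additive probability boost applied by every default rule.
#' @return Data frame with columns `trigger`, `target`, `boost`.
#' @export
default_correlation_rules <- function(boost = 0.15) {
  stopifnot(is.numeric(boost), boost >= 0, boost <= 1)
  data.frame(
    trigger = c("fatigue", "nausea", "diarrhea", "fatigue", "nausea",
                "vomiting", "fatigue", "nausea", "vomiting", "diarrhea"),
    target  = c("insomnia", "vomiting", "abdominal_pain", "cephalea",
                "cephalea", "cephalea", "pyrexia", "weight_loss",
                "weight_loss", "weight_loss"),
    boost   = boost,
    stringsAsFactors = FALSE
  )
}

#' Default within-week sampling order
#'
#' Symptoms are drawn sequentially within each week; a boost from a
#' correlation rule can only influence targets drawn after their trigger.
#' The default order therefore places every trigger symptom before all of
#' its targets.
#'
#' @return Character permutation of [symptom_names()].
#' @export
default_sampling_order <- function() {
  c("fatigue", "nausea", "vomiting", "diarrhea", "insomnia",
    "abdominal_pain", "cephalea", "hypertension", "pyrexia", "alopecia",
    "weight_loss")
}

#' Simulation configuration for the adverse-effect cohort generator
#'
#' Assembles and validates all parameters of the rule-based cohort
#' simulator: cohort dimensions, per-symptom baseline probabilities and
#' temporal modifiers, the bounded-Gaussian susceptibility distribution,
#' the trigger-target correlation rules, and the within-week sampling
#' order.
#'
#' @param n_patients Number of simulated patients (default 200).
#' @param n_weeks Number of monitored weeks per patient (default 6).
#' @param p_base Named probability vector over the symptom set.
#' @param temporal_modifiers Either `NULL` (all-ones profile), a single
#'   length-`n_weeks` nonnegative vector applied to every symptom, or a
#'   named list of per-symptom length-`n_weeks` vectors. The all-ones
#'   default reflects that no week-specific modifier values are published;
#'   see [cycle_ramp_modifiers()] for an explicitly non-default example.
#' @param susceptibility List with `mean`, `sd`, `lower`, `upper`, `method`
#'   (`"truncate"` or `"clip"`) describing the patient susceptibility
#'   factor distribution.
#' @param correlation_rules Data frame with columns `trigger`, `target`,
#'   `boost`.
#' @param sampling_order Character permutation of the symptom names.
#' @param bmi_range Range of the uniform baseline BMI draw (kg/m^2), used
#'   by the weight-loss detector thresholds, not by the panel simulation.
#' @param seed Integer root seed; per-patient substreams are derived from
#'   it so earlier patients are unchanged when the cohort grows.
#' @return Object of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 200,
                       n_weeks = 6,
                       p_base = default_p_base(),
                       temporal_modifiers = NULL,
                       susceptibility = list(mean = 1.0, sd = 0.20,
                                             lower = 0.5, upper = 1.8,
                                             method = "truncate"),
                       correlation_rules = default_correlation_rules(),
                       sampling_order = default_sampling_order(),
                       bmi_range = c(18, 32),
                       seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("`n_patients` must be >= 1", call. = FALSE)
  if (!is.numeric(n_weeks) || n_weeks < 1)
    stop("`n_weeks` must be >= 1", call. = FALSE)
  n_patients <- as.integer(n_patients)
  n_weeks <- as.integer(n_weeks)

  symptoms <- names(p_base)
  if (is.null(symptoms) || any(!nzchar(symptoms)))
    stop("`p_base` must be a named vector", call. = FALSE)
  if (any(p_base < 0 | p_base > 1))
    stop("`p_base` values must lie in [0, 1]", call. = FALSE)

  tm <- normalize_temporal_modifiers(temporal_modifiers, symptoms, n_weeks)

  susceptibility$method <- match.arg(susceptibility$method %||% "truncate",
                                     c("truncate", "clip"))
  validate_susceptibility(susceptibility)

  validate_rules(correlation_rules, symptoms)

  if (!setequal(sampling_order, symptoms) ||
      length(sampling_order) != length(symptoms))
    stop("`sampling_order` must be a permutation of the symptom names",
         call. = FALSE)

  stopifnot(length(bmi_range) == 2, bmi_range[1] > 0,
            bmi_range[1] < bmi_range[2])

  structure(
    list(n_patients = n_patients, n_weeks = n_weeks, p_base = p_base,
         temporal_modifiers = tm, susceptibility = susceptibility,
         correlation_rules = correlation_rules,
         sampling_order = sampling_order, bmi_range = bmi_range,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

normalize_temporal_modifiers <- function(tm, symptoms, n_weeks) {
  if (is.null(tm)) {
    tm <- rep(list(rep(1, n_weeks)), length(symptoms))
    names(tm) <- symptoms
    return(tm)
  }
  if (is.numeric(tm)) {
    tm <- rep(list(tm), length(symptoms))
    names(tm) <- symptoms
  }
  if (!all(symptoms %in% names(tm)))
    stop("temporal modifiers must cover every symptom", call. = FALSE)
  tm <- tm[symptoms]
  ok <- vapply(tm, function(v) length(v) == n_weeks && all(v >= 0),
               logical(1))
  if (!all(ok))
    stop("each temporal-modifier profile must have length `n_weeks` and be",
         " nonnegative", call. = FALSE)
  tm
}

validate_susceptibility <- function(s) {
  stopifnot(is.numeric(s$mean), is.numeric(s$sd), s$sd >= 0)
  if (!is.numeric(s$lower) || !is.numeric(s$upper) || s$lower >= s$upper)
    stop("susceptibility bounds must satisfy lower < upper", call. = FALSE)
  invisible(s)
}

validate_rules <- function(rules, symptoms) {
  stopifnot(is.data.frame(rules),
            all(c("trigger", "target", "boost") %in% names(rules)))
  unknown <- setdiff(unique(c(rules$trigger, rules$target)), symptoms)
  if (length(unknown))
    stop("correlation rule references unknown symptom(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(rules$trigger == rules$target))
    stop("correlation rules must have trigger != target", call. = FALSE)
  if (any(rules$boost < 0 | rules$boost > 1))
    stop("rule boosts must lie in [0, 1]", call. = FALSE)
  invisible(rules)
}

#' Example non-flat temporal modifier profile
#'
#' A simple treatment-cycle ramp in which symptom probabilities rise over
#' the first half of the monitoring horizon and plateau. No published
#' values exist for week-specific modifiers; this profile is provided
#' purely as a worked example of the configuration surface and is *not*
#' the default.
#'
#' @param n_weeks Horizon length.
#' @return Numeric vector of length `n_weeks`.
#' @export
cycle_ramp_modifiers <- function(n_weeks = 6) {
  pmin(1.2, 0.8 + 0.4 * (seq_len(n_weeks) - 1) / max(1, n_weeks - 1))
}

#' Read a simulation configuration from a YAML file
#'
#' The file may contain any subset of the [sim_config()] fields;
#' unspecified fields fall back to the defaults. `correlation_rules` is
#' given as a list of `{trigger, target, boost}` mappings and `p_base` as
#' a symptom-to-probability mapping.
#'
#' @param path Path to a YAML file.
#' @return Object of class `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (f in c("n_patients", "n_weeks", "seed", "bmi_range",
              "sampling_order")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$p_base)) args$p_base <- unlist(raw$p_base)
  if (!is.null(raw$temporal_modifiers))
    args$temporal_modifiers <- lapply(raw$temporal_modifiers, as.numeric)
  if (!is.null(raw$susceptibility)) {
    s <- list(mean = 1.0, sd = 0.20, lower = 0.5, upper = 1.8,
              method = "truncate")
    s[names(raw$susceptibility)] <- raw$susceptibility
    args$susceptibility <- s
  }
  if (!is.null(raw$correlation_rules)) {
    r <- raw$correlation_rules
    args$correlation_rules <- data.frame(
      trigger = vapply(r, `[[`, "", "trigger"),
      target = vapply(r, `[[`, "", "target"),
      boost = vapply(r, function(x) as.numeric(x$boost), numeric(1)),
      stringsAsFactors = FALSE)
  }
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Adverse-effect cohort simulation configuration\n")
  cat(sprintf("  patients: %d, weeks: %d, symptoms: %d\n",
              x$n_patients, x$n_weeks, length(x$p_base)))
  cat(sprintf("  susceptibility: N(%.2f, %.2f) on [%.2f, %.2f] (%s)\n",
              x$susceptibility$mean, x$susceptibility$sd,
              x$susceptibility$lower, x$susceptibility$upper,
              x$susceptibility$method))
  cat(sprintf("  correlation rules: %d, seed: %d\n",
              nrow(x$correlation_rules), x$seed))
  invisible(x)
}
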