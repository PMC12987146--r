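#' Rule configuration for the low-tolerance proxy label
#'
#' In clinical deployments the "low tolerance to current oncological
#' treatment" outcome is an expert annotation (CTCAE grade >= 2 effects
#' requiring treatment modification, dose reduction or delay, suspension,
#' or unplanned hospitalization). For synthetic cohorts no expert is
#' available, so the package provides a configurable rule-based surrogate
#' built from the weekly symptom panel. A week is labeled positive when
#' any of the following fires:
#' \itemize{
#'   \item the number of concurrent symptoms reaches
#'     `min_concurrent_symptoms`;
#'   \item any single symptom in `sentinel_symptoms` is present;
#'   \item all members of any set in `sentinel_combinations` co-occur;
#'   \item any symptom has been active for `persistence_weeks` consecutive
#'     weeks including the current one.
#' }
#'
#' The defaults (concurrency 6, the digestive triad
#' nausea+vomiting+diarrhea, the cachexia-like pair fatigue+weight loss,
#' 3-week persistence, no single-symptom sentinels) were calibrated once
#' so that the default simulated cohort carries a positive fraction close
#' to the ~63% observed in combined monitoring datasets; they are a
#' surrogate, not a clinical standard, and every piece is configurable.
#'
#' @param min_concurrent_symptoms Count of concurrent symptoms that alone
#'   implies low tolerance.
#' @param sentinel_symptoms Character vector of symptoms that alone imply
#'   low tolerance (default none).
#' @param sentinel_combinations List of character vectors; the
#'   simultaneous presence of all members of any set implies low
#'   tolerance.
#' @param persistence_weeks Consecutive active weeks of any one symptom
#'   that escalate to low tolerance.
#' @return Object of class `label_rules`.
#' @export
label_rules <- function(min_concurrent_symptoms = 6,
                        sentinel_symptoms = character(0),
                        sentinel_combinations = list(
                          c("nausea", "vomiting", "diarrhea"),
                          c("fatigue", "weight_loss")),
                        persistence_weeks = 3) {
  stopifnot(min_concurrent_symptoms >= 1, persistence_weeks >= 1)
  if (length(sentinel_combinations) &&
      any(!vapply(sentinel_combinations, length, integer(1))))
    stop("sentinel combinations must be non-empty sets", call. = FALSE)
  structure(
    list(min_concurrent_symptoms = as.integer(min_concurrent_symptoms),
         sentinel_symptoms = sentinel_symptoms,
         sentinel_combinations = sentinel_combinations,
         persistence_weeks = as.integer(persistence_weeks)),
    class = "label_rules"
  )
}

check_rule_symptoms <- function(rules, symptoms) {
  referenced <- unique(c(rules$sentinel_symptoms,
                         unlist(rules$sentinel_combinations)))
  unknown <- setdiff(referenced, symptoms)
  if (length(unknown))
    stop("label rule references unknown symptom(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(rules)
}

#' Label one patient-week observation
#'
#' Applies the rule-based low-tolerance surrogate to a single week of
#' symptom flags, given the patient's prior weeks (needed only by the
#' persistence rule). Deterministic.
#'
#' @param week_flags Named 0/1 vector of the current week's symptoms.
#' @param patient_history Matrix or data frame of prior weeks' flags with
#'   the same symptom columns, ordered oldest first; `NULL` for week 1.
#' @param rules A [label_rules()] object.
#' @return Integer 0 or 1.
#' @export
label_observation <- function(week_flags, patient_history = NULL,
                              rules = label_rules()) {
  symptoms <- names(week_flags)
  if (is.null(symptoms)) stop("`week_flags` must be named", call. = FALSE)
  check_rule_symptoms(rules, symptoms)
  flags <- as.integer(week_flags)
  names(flags) <- symptoms

  if (sum(flags) >= rules$min_concurrent_symptoms) return(1L)
  if (length(rules$sentinel_symptoms) &&
      any(flags[rules$sentinel_symptoms] == 1L)) return(1L)
  for (combo in rules$sentinel_combinations)
    if (all(flags[combo] == 1L)) return(1L)

  pw <- rules$persistence_weeks
  if (pw >= 1 && !is.null(patient_history) && nrow(patient_history) >= pw - 1) {
    hist <- as.matrix(patient_history)[, symptoms, drop = FALSE]
    recent <- rbind(hist, flags)
    recent <- recent[(nrow(recent) - pw + 1):nrow(recent), , drop = FALSE]
    if (any(colSums(recent) == pw)) return(1L)
  } else if (pw == 1 && any(flags == 1L)) {
    return(1L)
  }
  0L
}

#' Label every observation of a cohort
#'
#' Applies [label_observation()] to each patient-week of a simulated (or
#' detector-derived) cohort table, appending a `low_tolerance` column.
#' Labels attach per observation, matching the observation-level datasets
#' used by the alerting models.
#'
#' @param cohort Data frame with `patient_id`, `week` and one 0/1 column
#'   per symptom.
#' @param rules A [label_rules()] object.
#' @return The cohort with an integer `low_tolerance` column appended.
#' @export
label_cohort <- function(cohort, rules = label_rules()) {
  symptoms <- setdiff(names(cohort), c("patient_id", "week",
                                       "low_tolerance"))
  check_rule_symptoms(rules, symptoms)
  cohort <- cohort[order(cohort$patient_id, cohort$week), , drop = FALSE]
  labels <- integer(nrow(cohort))
  for (pid in unique(cohort$patient_id)) {
    idx <- which(cohort$patient_id == pid)
    m <- as.matrix(cohort[idx, symptoms, drop = FALSE])
    for (j in seq_along(idx)) {
      hist <- if (j > 1) m[seq_len(j - 1), , drop = FALSE] else NULL
      labels[idx[j]] <- label_observation(m[j, ], hist, rules)
    }
  }
  cohort$low_tolerance <- labels
  cohort
}
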