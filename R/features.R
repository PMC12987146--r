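#' Count of distinct symptoms in a week
#'
#' @param week_flags 0/1 vector of the 11 symptom flags.
#' @return Integer count.
#' @export
weekly_symptom_count <- function(week_flags) {
  as.integer(sum(week_flags > 0))
}

#' Cumulative symptom load up to the current week
#'
#' Total number of symptom-weeks reported by the patient from the start
#' of monitoring through the current week.
#'
#' @param history Matrix or data frame of weekly 0/1 flags, oldest first,
#'   *including* the current week; may have zero rows.
#' @return Integer count.
#' @export
cumulative_symptom_load <- function(history) {
  if (is.null(history) || NROW(history) == 0) return(0L)
  as.integer(sum(as.matrix(history) > 0))
}

#' Consecutive-week duration of a symptom
#'
#' Length of the run of active weeks for one symptom ending at the
#' current week; 0 when the symptom is currently inactive.
#'
#' @param symptom_name Column to evaluate.
#' @param history Matrix or data frame of weekly flags, oldest first,
#'   including the current week.
#' @return Integer run length.
#' @export
symptom_duration <- function(symptom_name, history) {
  h <- as.matrix(history)
  if (!symptom_name %in% colnames(h))
    stop("unknown symptom: ", symptom_name, call. = FALSE)
  col <- rev(h[, symptom_name])
  run <- 0L
  for (v in col) {
    if (v > 0) run <- run + 1L else break
  }
  run
}

#' Clinically motivated symptom interaction flags
#'
#' Binary co-occurrence indicators for three symptom clusters: digestive
#' (nausea AND vomiting AND diarrhea), systemic (fatigue AND weight
#' loss), neurological (cephalea AND hypertension).
#'
#' @param week_flags Named 0/1 vector of the 11 symptoms.
#' @return Named integer vector `c(ix_digestive, ix_systemic,
#'   ix_neurological)`.
#' @export
interaction_flags <- function(week_flags) {
  f <- week_flags
  c(ix_digestive = as.integer(f[["nausea"]] > 0 & f[["vomiting"]] > 0 &
                                f[["diarrhea"]] > 0),
    ix_systemic = as.integer(f[["fatigue"]] > 0 & f[["weight_loss"]] > 0),
    ix_neurological = as.integer(f[["cephalea"]] > 0 &
                                   f[["hypertension"]] > 0))
}

#' Feature-column manifest
#'
#' Names of the 30 model-input columns: the 11 raw weekly symptom flags
#' plus 19 engineered features — current weekly symptom count, cumulative
#' symptom load, 11 per-symptom consecutive-week durations, 3 interaction
#' flags, previous-week symptom count, week-over-week count change, and
#' the longest single-symptom streak observed so far. The published
#' description enumerates the first 16 engineered features by category
#' only; the final three are this package's documented reconstruction of
#' the remaining count, and the builder accepts any subset via
#' `manifest`.
#'
#' @return Character vector of length 30.
#' @export
feature_manifest <- function() {
  c(symptom_names(),
    "weekly_symptom_count", "cumulative_symptom_load",
    paste0("duration_", symptom_names()),
    "ix_digestive", "ix_systemic", "ix_neurological",
    "prev_week_symptom_count", "symptom_count_change",
    "longest_symptom_streak")
}

#' Build the model-input feature matrix
#'
#' Expands a weekly symptom panel into the 30-column model input (raw
#' flags plus engineered dynamics), keyed by patient and week. The
#' `low_tolerance` label column is carried through when present.
#'
#' @param cohort Data frame with `patient_id`, `week`, one 0/1 column per
#'   symptom, and optionally `low_tolerance`.
#' @param manifest Character vector of feature columns to emit (default
#'   the full [feature_manifest()]).
#' @return Data frame with `patient_id`, `week`, the manifest columns,
#'   and `low_tolerance` if present in the input.
#' @export
build_feature_matrix <- function(cohort, manifest = feature_manifest()) {
  symptoms <- intersect(symptom_names(), names(cohort))
  if (!length(symptoms)) stop("no symptom columns found", call. = FALSE)
  if (anyDuplicated(cohort[c("patient_id", "week")]))
    stop("duplicate (patient_id, week) keys", call. = FALSE)
  cohort <- cohort[order(cohort$patient_id, cohort$week), , drop = FALSE]

  n <- nrow(cohort)
  eng <- matrix(0L, n, 19, dimnames = list(NULL, setdiff(
    feature_manifest(), symptom_names())))

  for (pid in unique(cohort$patient_id)) {
    idx <- which(cohort$patient_id == pid)
    m <- as.matrix(cohort[idx, symptoms, drop = FALSE])
    counts <- as.integer(rowSums(m))
    streak <- matrix(0L, length(idx), length(symptoms))
    for (j in seq_along(idx)) {
      streak[j, ] <- if (j == 1) m[1, ] else (streak[j - 1, ] + 1L) * m[j, ]
      r <- idx[j]
      eng[r, "weekly_symptom_count"] <- counts[j]
      eng[r, "cumulative_symptom_load"] <- sum(counts[seq_len(j)])
      eng[r, paste0("duration_", symptoms)] <- streak[j, ]
      eng[r, c("ix_digestive", "ix_systemic", "ix_neurological")] <-
        interaction_flags(m[j, ])
      eng[r, "prev_week_symptom_count"] <- if (j > 1) counts[j - 1] else 0L
      eng[r, "symptom_count_change"] <-
        counts[j] - eng[r, "prev_week_symptom_count"]
      eng[r, "longest_symptom_streak"] <-
        max(streak[seq_len(j), , drop = FALSE])
    }
  }

  out <- cbind(cohort[c("patient_id", "week")],
               cohort[symptoms],
               as.data.frame(eng))
  out <- out[c("patient_id", "week", manifest)]
  if ("low_tolerance" %in% names(cohort))
    out$low_tolerance <- cohort$low_tolerance
  out
}
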