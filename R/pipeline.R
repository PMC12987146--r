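#' Patient-wise train/test partition
#'
#' Splits a cohort's patients into a held-out test group and a training
#' pool so that no patient contributes observations to both sides — the
#' standard leakage guard for longitudinal clinical data. The test group
#' size is `test_fraction` of the patients, rounded half away from zero.
#'
#' @param cohort Data frame with a `patient_id` column.
#' @param test_fraction Fraction of patients held out (default 0.30);
#'   must lie strictly in (0, 1).
#' @param seed Integer seed for the random assignment.
#' @return List with character vectors `test` and `pool` of patient ids.
#' @export
split_patients <- function(cohort, test_fraction = 0.30, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 ||
      test_fraction >= 1)
    stop("`test_fraction` must lie in (0, 1)", call. = FALSE)
  ids <- sort(unique(cohort$patient_id))
  n_test <- as.integer(round_half_away(test_fraction * length(ids)))
  n_test <- max(1L, min(length(ids) - 1L, n_test))
  set.seed(seed)
  test <- sort(sample(ids, n_test))
  list(test = test, pool = setdiff(ids, test))
}

#' Observation-level train/validation split
#'
#' Randomly splits the non-test patients' observations into training and
#' validation rows at the given fraction (80/20 by default). Unlike
#' [split_patients()] this split is at the observation level: validation
#' rows come from the same patients as training rows.
#'
#' @param observations Data frame of pool observations.
#' @param train_fraction Fraction of rows used for training.
#' @param seed Integer seed.
#' @return List with data frames `train` and `validation`.
#' @export
split_observations <- function(observations, train_fraction = 0.80,
                               seed = 1L) {
  if (nrow(observations) == 0)
    stop("no observations to split", call. = FALSE)
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop("`train_fraction` must lie in (0, 1)", call. = FALSE)
  n <- nrow(observations)
  n_train <- as.integer(round_half_away(train_fraction * n))
  n_train <- max(1L, min(n - 1L, n_train))
  set.seed(seed)
  tr <- sort(sample(n, n_train))
  list(train = observations[tr, , drop = FALSE],
       validation = observations[-tr, , drop = FALSE])
}

#' Fit a min-max scaler on training features
#'
#' Learns per-column minima and maxima from the training matrix only, so
#' no information from validation or test rows leaks into preprocessing.
#'
#' @param x Numeric data frame or matrix of training features.
#' @return Object of class `minmax_scaler`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Maps each feature through `(x - min) / (max - min)` with the training
#' extrema. Training columns land in \[0, 1\]; constant training columns
#' map to 0; out-of-range values on new data are left unclipped.
#'
#' @param scaler A [fit_scaler()] result.
#' @param x Data frame or matrix with the same columns.
#' @return Scaled numeric matrix.
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)[, names(scaler$min), drop = FALSE]
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1
  sweep(sweep(x, 2, scaler$min), 2, rng, "/")
}

#' Train an alerting classifier
#'
#' Fits one of four classifier families on a scaled feature matrix with
#' binary labels; every family exposes scores on \[0, 1\] through
#' [score_classifier()] so the decision threshold `t_C` is meaningful
#' across families:
#' \describe{
#'   \item{logistic}{[stats::glm()] with a binomial link; scores are
#'     fitted probabilities.}
#'   \item{svm}{radial-kernel [e1071::svm()]; the decision margin is
#'     passed through a monotone logistic link fitted on the training
#'     margins (Platt-style), since a raw margin is not a probability.}
#'   \item{random_forest}{probability forest via [ranger::ranger()].}
#'   \item{gbm}{gradient-boosted trees via [xgboost::xgboost()] with a
#'     logistic objective.}
#' }
#' Defaults are fixed, sensible settings per family (single-threaded and
#' seeded, so fits are reproducible); `params` overrides them.
#'
#' @param x Scaled numeric feature matrix or data frame.
#' @param y Binary 0/1 label vector with both classes present.
#' @param family One of `"logistic"`, `"svm"`, `"random_forest"`,
#'   `"gbm"`.
#' @param params Named list of family-specific overrides (`cost`,
#'   `gamma`; `num_trees`, `mtry`; `nrounds`, `eta`, `max_depth`).
#' @param seed Integer seed.
#' @return Object of class `tolerance_model`.
#' @export
train_classifier <- function(x, y,
                             family = c("logistic", "svm",
                                        "random_forest", "gbm"),
                             params = list(), seed = 1L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("training labels contain a single class", call. = FALSE)
  set.seed(seed)

  fit <- switch(
    family,
    logistic = {
      df <- as.data.frame(x)
      df$.y <- y
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    svm = {
      m <- e1071::svm(x, factor(y, levels = c(0, 1)),
                      kernel = "radial",
                      cost = params$cost %||% 1,
                      gamma = params$gamma %||% (1 / ncol(x)),
                      scale = FALSE)
      margin <- as.numeric(attr(
        predict(m, x, decision.values = TRUE), "decision.values"))
      link <- suppressWarnings(
        glm(y ~ margin, family = binomial(),
            data = data.frame(y = y, margin = margin)))
      list(svm = m, link = link)
    },
    random_forest = ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)),
      num.trees = params$num_trees %||% 500,
      mtry = params$mtry %||% max(1, floor(sqrt(ncol(x)))),
      probability = TRUE, seed = seed, num.threads = 1),
    gbm = xgboost::xgboost(
      x = x, y = factor(y, levels = c(0, 1)),
      nrounds = params$nrounds %||% 150,
      learning_rate = params$eta %||% 0.1,
      max_depth = params$max_depth %||% 3,
      nthreads = 1, seed = seed, verbosity = 0)
  )
  structure(list(family = family, fit = fit, features = colnames(x),
                 seed = seed),
            class = "tolerance_model")
}

#' Score observations with a trained classifier
#'
#' @param model A [train_classifier()] result.
#' @param x Feature matrix or data frame (same columns as training).
#' @return Numeric scores in \[0, 1\], one per row.
#' @export
score_classifier <- function(model, x) {
  x <- as.matrix(x)[, model$features, drop = FALSE]
  switch(
    model$family,
    logistic = as.numeric(predict(model$fit, as.data.frame(x),
                                  type = "response")),
    svm = {
      margin <- as.numeric(attr(
        predict(model$fit$svm, x, decision.values = TRUE),
        "decision.values"))
      as.numeric(predict(model$fit$link,
                         data.frame(margin = margin),
                         type = "response"))
    },
    random_forest = as.numeric(
      predict(model$fit, data = x, num.threads = 1)$predictions[, "1"]),
    gbm = as.numeric(predict(model$fit, x))
  )
}

#' Threshold a score vector into alert decisions
#'
#' An alert is issued when the score strictly exceeds the decision
#' threshold `t_C` (default 0.5).
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param t_c Decision threshold.
#' @return Integer 0/1 vector.
#' @export
classify <- function(scores, t_c = 0.5) {
  as.integer(scores > t_c)
}

#' Evaluate alert predictions
#'
#' Computes the confusion matrix and the standard binary-classification
#' metrics: accuracy, precision, recall (sensitivity), specificity,
#' F1-score, and — when scores are supplied — AUC-ROC with the ROC
#' points. Ratios with zero denominators are reported as `NA`, never
#' coerced to 0.
#'
#' @param predicted Integer 0/1 predictions.
#' @param truth Integer 0/1 ground-truth labels.
#' @param scores Optional numeric scores for AUC/ROC.
#' @param t_c Decision threshold recorded in the report.
#' @return Object of class `tolerance_eval`: a list with `metrics`
#'   (named numeric), `confusion` (`tp`, `fp`, `tn`, `fn`), `roc`
#'   (data frame or `NULL`), `t_c`, `n`.
#' @export
evaluate_predictions <- function(predicted, truth, scores = NULL,
                                 t_c = 0.5) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  tn <- sum(predicted == 0 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_

  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- if (!is.na(precision) && !is.na(recall) &&
            (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else NA_real_

  auc <- NA_real_
  roc_points <- NULL
  if (!is.null(scores) && length(unique(truth)) == 2) {
    r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(r))
    roc_points <- data.frame(fpr = 1 - r$specificities,
                             tpr = r$sensitivities)
    roc_points <- roc_points[order(roc_points$fpr, roc_points$tpr), ]
  }

  structure(
    list(metrics = c(accuracy = safe_div(tp + tn, tp + fp + tn + fn),
                     precision = precision, recall = recall,
                     specificity = specificity, f1 = f1, auc_roc = auc),
         confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
         roc = roc_points, t_c = t_c, n = length(truth)),
    class = "tolerance_eval")
}

#' @export
print.tolerance_eval <- function(x, ...) {
  cat(sprintf("Alert-model evaluation (n = %d, t_C = %.2f)\n", x$n, x$t_c))
  print(round(x$metrics, 3))
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$confusion["tp"], x$confusion["fp"],
              x$confusion["tn"], x$confusion["fn"]))
  invisible(x)
}

#' Decision-threshold sweep
#'
#' Re-thresholds a fixed score vector over a grid of `t_C` values and
#' evaluates each choice, exposing the recall/specificity trade-off that
#' guides the operating-point selection of a screening alert system.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param truth Integer 0/1 labels.
#' @param grid Thresholds to evaluate (default 0.1 to 0.9 by 0.1).
#' @return Data frame with one row per threshold: `threshold`,
#'   `accuracy`, `precision`, `recall`, `specificity`, `f1`, `auc_roc`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
threshold_sweep <- function(scores, truth, grid = seq(0.1, 0.9, by = 0.1)) {
  rows <- lapply(grid, function(tc) {
    ev <- evaluate_predictions(classify(scores, tc), truth,
                               scores = scores, t_c = tc)
    data.frame(threshold = tc, t(ev$metrics), t(ev$confusion))
  })
  do.call(rbind, rows)
}

#' Run the full alerting pipeline on a labeled feature matrix
#'
#' Convenience wrapper chaining the patient-wise test split, the
#' observation-level train/validation split, min-max scaling fitted on
#' the training rows, classifier training, and evaluation on the
#' validation and test sets.
#'
#' @param features Feature matrix from [build_feature_matrix()] with a
#'   `low_tolerance` column.
#' @param family Classifier family, see [train_classifier()].
#' @param test_fraction,train_fraction Split fractions.
#' @param t_c Decision threshold.
#' @param params Hyperparameter overrides.
#' @param seed Integer seed driving both splits and the fit.
#' @return List with `model`, `scaler`, `split` (row counts), and
#'   `tolerance_eval` objects `validation` and `test`.
#' @export
run_alert_pipeline <- function(features, family = "gbm",
                               test_fraction = 0.30,
                               train_fraction = 0.80, t_c = 0.5,
                               params = list(), seed = 1L) {
  stopifnot("low_tolerance" %in% names(features))
  fcols <- setdiff(names(features),
                   c("patient_id", "week", "low_tolerance"))
  parts <- split_patients(features, test_fraction, seed = seed)
  pool <- features[features$patient_id %in% parts$pool, , drop = FALSE]
  test <- features[features$patient_id %in% parts$test, , drop = FALSE]
  obs <- split_observations(pool, train_fraction, seed = seed)

  scaler <- fit_scaler(obs$train[fcols])
  xtr <- apply_scaler(scaler, obs$train[fcols])
  xva <- apply_scaler(scaler, obs$validation[fcols])
  xte <- apply_scaler(scaler, test[fcols])

  model <- train_classifier(xtr, obs$train$low_tolerance, family,
                            params = params, seed = seed)
  sva <- score_classifier(model, xva)
  ste <- score_classifier(model, xte)

  list(
    model = model, scaler = scaler,
    split = c(train = nrow(obs$train), validation = nrow(obs$validation),
              test = nrow(test)),
    validation = evaluate_predictions(classify(sva, t_c),
                                      obs$validation$low_tolerance,
                                      scores = sva, t_c = t_c),
    test = evaluate_predictions(classify(ste, t_c), test$low_tolerance,
                                scores = ste, t_c = t_c)
  )
}
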