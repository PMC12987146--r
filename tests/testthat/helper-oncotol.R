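# Independent quadrature oracle for the mean of a Gaussian restricted to
# [lower, upper]; used to predict susceptibility-scaled prevalences
# without going through the package's own susceptibility_mean().
truncnorm_mean_oracle <- function(mean, sd, lower, upper) {
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd) / z,
                   lower, upper)$value
}

# named all-zero symptom week
zero_week <- function() {
  stats::setNames(integer(length(symptom_names())), symptom_names())
}

week_with <- function(...) {
  w <- zero_week()
  w[c(...)] <- 1L
  w
}

# flat sleep week at exactly the baseline statistics
flat_sleep_week <- function(duration = 7.5, efficiency = 93,
                            deep = 20, rem = 21) {
  data.frame(night = 1:7, duration = duration, efficiency = efficiency,
             deep_fraction = deep, rem_fraction = rem)
}

flat_sleep_baseline <- function(duration = 7.5, efficiency = 93,
                                deep = 20, rem = 21) {
  list(duration = duration, efficiency = efficiency,
       deep_fraction = deep, rem_fraction = rem)
}

# skin-temperature series builder: one value per 10-minute sample across
# 7 nightly sessions, with an optional override window
temp_series <- function(base = 36.8, override_night = NULL,
                        override_samples = NULL, override_temp = NULL) {
  per_night <- 49
  night <- rep(1:7, each = per_night)
  within <- rep(seq_len(per_night) - 1, times = 7) * 600
  temperature <- rep(base, length(night))
  if (!is.null(override_night)) {
    idx <- which(night == override_night)[override_samples]
    temperature[idx] <- override_temp
  }
  data.frame(night = night,
             time = (night - 1) * 86400 + within,
             temperature = temperature)
}
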