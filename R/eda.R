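#' Per-symptom prevalence of a cohort
#'
#' Percentage of patient-week observations in which each symptom flag is
#' set.
#'
#' @param cohort Data frame with one 0/1 column per symptom (plus any key
#'   columns).
#' @return Named numeric vector of percentages.
#' @export
prevalence <- function(cohort) {
  symptoms <- intersect(symptom_names(), names(cohort))
  if (!length(symptoms) || nrow(cohort) == 0)
    stop("cohort has no symptom observations", call. = FALSE)
  vapply(cohort[symptoms], function(col) 100 * mean(col > 0), numeric(1))
}

#' 2x2 contingency table of two binary vectors
#'
#' @param x,y Binary 0/1 vectors of equal length.
#' @return Named counts `c(a, b, c, d)`: both present, first only, second
#'   only, neither.
#' @export
contingency_2x2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  x <- x > 0
  y <- y > 0
  c(a = sum(x & y), b = sum(x & !y), c = sum(!x & y), d = sum(!x & !y))
}

#' Phi coefficient of a 2x2 table
#'
#' Pearson correlation specialized to two binary variables:
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`. Tables with a zero
#' marginal (a variable that never varies) have no defined association
#' and return `NA`.
#'
#' @param a,b,c,d Cell counts: both present, first only, second only,
#'   neither. `a` may instead be a length-4 vector or 2x2 matrix in that
#'   cell order.
#' @return Phi in \[-1, 1\], or `NA` for degenerate tables.
#' @export
phi_coefficient <- function(a, b = NULL, c = NULL, d = NULL) {
  k <- unpack_2x2(a, b, c, d)
  marg <- c(k[1] + k[2], k[3] + k[4], k[1] + k[3], k[2] + k[4])
  if (any(marg == 0)) return(NA_real_)
  (k[1] * k[4] - k[2] * k[3]) / sqrt(prod(marg))
}

unpack_2x2 <- function(a, b, c, d) {
  if (is.null(b)) {
    cells <- as.numeric(a)
    if (length(cells) != 4)
      stop("expected 4 cell counts", call. = FALSE)
  } else {
    cells <- as.numeric(c(a, b, c, d))
  }
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  cells
}

#' Pearson chi-squared test of independence on a 2x2 table
#'
#' The 1-degree-of-freedom Pearson statistic without continuity
#' correction (matching the identity `chi2 = n * phi^2`); a Yates
#' correction can be switched on. Tables with a zero marginal (an
#' expected cell count of 0) are degenerate and return `NA` for both the
#' statistic and the p-value.
#'
#' @inheritParams phi_coefficient
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return List with `statistic`, `p_value`, `n`.
#' @export
chi2_independence <- function(a, b = NULL, c = NULL, d = NULL,
                              correct = FALSE) {
  cells <- unpack_2x2(a, b, c, d)
  n <- sum(cells)
  phi <- phi_coefficient(cells)
  if (is.na(phi))
    return(list(statistic = NA_real_, p_value = NA_real_, n = n))
  if (correct) {
    k <- cells
    marg <- (k[1] + k[2]) * (k[3] + k[4]) * (k[1] + k[3]) * (k[2] + k[4])
    stat <- n * (max(0, abs(k[1] * k[4] - k[2] * k[3]) - n / 2))^2 / marg
  } else {
    stat <- n * phi^2
  }
  list(statistic = stat, p_value = pchisq(stat, df = 1,
                                          lower.tail = FALSE), n = n)
}

#' Symptom co-occurrence report
#'
#' Evaluates every unordered pair of symptoms over the cohort's
#' patient-week observations: the phi correlation matrix, the full
#' pair table with chi-squared statistics, and the subset significant at
#' `alpha`. Raw p-values are reported by default (`adjust = "none"`), in
#' line with conventional per-pair screening; any [stats::p.adjust()]
#' method (e.g. `"bonferroni"`) can be requested instead.
#'
#' @param cohort Data frame with one 0/1 column per symptom.
#' @param alpha Significance level (default 0.05).
#' @param correct Yates continuity correction flag, see
#'   [chi2_independence()].
#' @param adjust Multiple-testing adjustment method (default `"none"`).
#' @return List with `phi_matrix` (symmetric, unit diagonal), `pairs`
#'   (data frame `symptom_1`, `symptom_2`, `phi`, `chi2`, `p_value`),
#'   and `significant` (subset with adjusted p < alpha, sorted by
#'   p-value).
#' @export
cooccurrence_report <- function(cohort, alpha = 0.05, correct = FALSE,
                                adjust = "none") {
  symptoms <- intersect(symptom_names(), names(cohort))
  if (!length(symptoms) || nrow(cohort) == 0)
    stop("cohort has no symptom observations", call. = FALSE)
  m <- length(symptoms)
  phi_matrix <- matrix(NA_real_, m, m,
                       dimnames = list(symptoms, symptoms))
  diag(phi_matrix) <- 1
  pairs <- expand.grid(i = seq_len(m), j = seq_len(m))
  pairs <- pairs[pairs$i < pairs$j, ]
  res <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$i[r]; j <- pairs$j[r]
    tab <- contingency_2x2(cohort[[symptoms[i]]], cohort[[symptoms[j]]])
    phi <- phi_coefficient(tab)
    chi <- chi2_independence(tab, correct = correct)
    data.frame(symptom_1 = symptoms[i], symptom_2 = symptoms[j],
               phi = phi, chi2 = chi$statistic, p_value = chi$p_value,
               stringsAsFactors = FALSE)
  })
  pairs_df <- do.call(rbind, res)
  pairs_df$p_adjusted <- stats::p.adjust(pairs_df$p_value,
                                         method = adjust)
  for (r in seq_len(nrow(pairs_df))) {
    phi_matrix[pairs_df$symptom_1[r], pairs_df$symptom_2[r]] <-
      pairs_df$phi[r]
    phi_matrix[pairs_df$symptom_2[r], pairs_df$symptom_1[r]] <-
      pairs_df$phi[r]
  }
  sig <- pairs_df[!is.na(pairs_df$p_adjusted) &
                    pairs_df$p_adjusted < alpha, , drop = FALSE]
  sig <- sig[order(sig$p_value), , drop = FALSE]
  list(phi_matrix = phi_matrix, pairs = pairs_df, significant = sig)
}
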