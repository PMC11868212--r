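#' Atypical-high outlier threshold
#'
#' The upper-fence rule used for concentration batch summaries:
#' \eqn{Q_3 + 1.5 (Q_3 - Q_1)}.
#'
#' @param q1,q3 First and third quartiles.
#' @return The threshold (same units as the quartiles).
#' @export
#' @examples
#' atypical_threshold(0.453, 0.477)  # 0.513
atypical_threshold <- function(q1, q3) {
  q3 + 1.5 * (q3 - q1)
}

#' Summary statistics for a concentration batch
#'
#' Elementary statistics of a vector of concentrations (a certified
#' reference material series, or a full sampling campaign): order statistics,
#' mean and sample SD, coefficient of variation, max/min ratio, and the
#' atypical-high threshold \eqn{Q_3 + 1.5(Q_3 - Q_1)} with the count of
#' values strictly above it. Quartiles use linear interpolation of order
#' statistics at probability `p (n - 1) + 1` ([stats::quantile()] type 7);
#' published thresholds computed from rounded quartiles can differ in the
#' last digit, so the convention is configurable.
#'
#' @param values Positive concentrations (the max/min ratio is undefined —
#'   `NA` with a warning — if any value is not positive).
#' @param quantile_type Quantile convention passed to [stats::quantile()].
#' @return A one-row tibble of class `batch_summary`: `n`, `min`, `q1`,
#'   `median`, `q3`, `max`, `mean`, `sd`, `cv_percent`, `ratio_max_min`,
#'   `atypical_threshold`, `n_above_threshold`.
#' @export
summarize_batch <- function(values, quantile_type = 7) {
  if (length(values) < 1) abort("`values` is empty.")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = quantile_type))
  mn <- mean(values)
  s <- if (length(values) > 1) sd(values) else 0
  ratio <- if (any(values <= 0)) {
    warn("non-positive values: max/min ratio undefined.")
    NA_real_
  } else {
    max(values) / min(values)
  }
  thr <- atypical_threshold(q[1], q[3])
  out <- tibble::tibble(
    n = length(values),
    min = min(values), q1 = q[1], median = q[2], q3 = q[3],
    max = max(values),
    mean = mn, sd = s,
    cv_percent = 100 * s / mn,
    ratio_max_min = ratio,
    atypical_threshold = thr,
    n_above_threshold = sum(values > thr)
  )
  class(out) <- c("batch_summary", class(out))
  out
}

#' Check a batch against a certified reference value
#'
#' Passes when the measured interval `mean +/- sd` overlaps the certified
#' interval `reference_mean +/- reference_sd`, the acceptance rule used when
#' validating reference-material series.
#'
#' @param summary A `batch_summary` (from [summarize_batch()]), or any list
#'   with `mean` and `sd`.
#' @param reference_mean,reference_sd Certified value and its SD.
#' @return A one-row tibble: measured and reference values, the gap between
#'   means, and `pass`.
#' @export
#' @examples
#' crm_check(summarize_batch(c(0.44, 0.46, 0.47, 0.50)), 0.454, 0.019)
crm_check <- function(summary, reference_mean, reference_sd) {
  mn <- summary$mean
  s <- summary$sd
  gap <- abs(mn - reference_mean)
  tibble::tibble(
    measured_mean = mn, measured_sd = s,
    reference_mean = reference_mean, reference_sd = reference_sd,
    mean_gap = gap,
    pass = gap <= s + reference_sd
  )
}
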