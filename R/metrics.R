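# Model scoring: the correlation coefficient q2, the external r2, and the
# acceptance rule.

#' Correlation coefficient q2
#'
#' `q2 = 1 - sum((h - y)^2) / sum((y - mean(y))^2)`.  Equals 1 at perfect
#' prediction, 0 for the mean predictor, and can be arbitrarily negative
#' for predictors worse than the mean.  This is the fitted-set statistic
#' (no resampling), the quantity the training cost maximises.
#'
#' @param y Observed activities (length >= 2, non-constant).
#' @param h Predicted activities.
#' @return A single number <= 1.
#' @examples
#' q_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
q_squared <- function(y, h) {
  stopifnot(length(y) == length(h))
  if (length(y) < 2L) {
    abort("q2 needs at least two observations.",
          class = "qsardnn_validation_error")
  }
  ssy <- sum((y - mean(y))^2)
  if (ssy <= 0) {
    abort("q2 is undefined for constant observed activity.",
          class = "qsardnn_validation_error")
  }
  1 - sum((h - y)^2) / ssy
}

#' External r2
#'
#' Squared Pearson correlation between observed and predicted activities,
#' the standard external-validation statistic in QSAR.  Invariant under
#' affine transforms of either argument, hence blind to calibration bias
#' -- which is exactly why it is reported alongside q2 rather than instead
#' of it.  The `reference_mean` variant computes a coefficient of
#' determination about a supplied mean (e.g. the training-set mean)
#' instead.
#'
#' @param y Observed activities (length >= 3, non-constant).
#' @param h Predicted activities.
#' @param reference_mean Optional: compute
#'   `1 - sum((h - y)^2) / sum((y - reference_mean)^2)` instead of the
#'   squared correlation.
#' @return A single number; the Pearson form lies in \[0, 1\].
#' @export
r_squared <- function(y, h, reference_mean = NULL) {
  stopifnot(length(y) == length(h))
  if (length(y) < 3L) {
    abort("r2 needs at least three observations.",
          class = "qsardnn_validation_error")
  }
  if (var(y) <= 0) {
    abort("r2 is undefined for constant observed activity.",
          class = "qsardnn_validation_error")
  }
  if (!is.null(reference_mean)) {
    return(1 - sum((h - y)^2) / sum((y - reference_mean)^2))
  }
  if (var(h) <= 0) {
    warn("Predictions are constant; r2 reported as 0.")
    return(0)
  }
  cor(y, h)^2
}

model_report <- function(q2_train, q2_test, r2_test, n_train, n_test,
                         descriptors, stopping_epoch) {
  list(q2_train = q2_train, q2_test = q2_test, r2_test = r2_test,
       n_train = n_train, n_test = n_test, descriptors = descriptors,
       stopping_epoch = stopping_epoch)
}

#' Model acceptance rule
#'
#' A model is acceptable when its training-set q2 and its external-test r2
#' both clear their thresholds; the defaults are q2 >= 0.60 and
#' r2 >= 0.55, both inclusive.
#'
#' @param report A model report (from [train_qsar()]`$report` or
#'   [glance()]), or any list with `q2_train` and `r2_test`.
#' @param q2_threshold,r2_threshold Thresholds; defaults 0.60 / 0.55.
#' @return `TRUE` or `FALSE`.
#' @export
accept_model <- function(report, q2_threshold = 0.60, r2_threshold = 0.55) {
  isTRUE(report$q2_train >= q2_threshold) &&
    isTRUE(report$r2_test >= r2_threshold)
}
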