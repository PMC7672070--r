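#' Fit the linear age-bias correction on the training split
#'
#' Deep age regressors show regression-to-the-mean: subjects older than
#' the cohort average are predicted too young and vice versa. The
#' correction regresses the raw prediction on chronological age,
#' `raw_pred = alpha + beta * age + e`, on the training split only, and
#' is later inverted (default) or subtracted so that corrected
#' predictions are unbiased in age on independent data.
#'
#' @param raw_preds_train raw model predictions (years) on the training
#'   split.
#' @param ages_train chronological ages (years), non-constant, n >= 3.
#' @return a `bias_correction`: list with `alpha` (intercept, years) and
#'   `beta` (slope, dimensionless).
#' @export
fit_bias_correction <- function(raw_preds_train, ages_train) {
  n <- length(raw_preds_train)
  stopifnot(length(ages_train) == n)
  if (n < 3L) stop_bad_arg("need >= 3 training subjects")
  if (sd(ages_train) == 0)
    stop_bad_arg("constant training ages: slope undefined")
  fit <- lm(raw_preds_train ~ ages_train)
  cf <- coef(fit)
  structure(list(alpha = unname(cf[1L]), beta = unname(cf[2L])),
            class = "bias_correction")
}

#' Apply a fitted bias correction and compute brain-age differences
#'
#' With the default `method = "invert"`, the corrected prediction is
#' `(raw_pred - alpha) / beta`, which makes a perfect-after-correction
#' predictor exactly unbiased. `method = "residual"` instead subtracts
#' the fitted age trend, `raw_pred - (alpha + beta * age) + age`. The
#' brain-age difference is `delta = corrected_pred - age` in both cases.
#'
#' @param bc a [fit_bias_correction()] result.
#' @param raw_preds raw predictions (years), aligned with `ages`.
#' @param ages chronological ages (years).
#' @param subject_ids optional ids (default `S0001`, ...).
#' @param method `"invert"` (default) or `"residual"`.
#' @return a `data.frame` of prediction records: `subject_id`, `age`,
#'   `raw_pred`, `corrected_pred`, `delta`.
#' @export
apply_bias_correction <- function(bc, raw_preds, ages, subject_ids = NULL,
                                  method = c("invert", "residual")) {
  stopifnot(inherits(bc, "bias_correction"),
            length(raw_preds) == length(ages))
  method <- match.arg(method)
  if (method == "invert" && abs(bc$beta) < .Machine$double.eps)
    stop_bad_arg("bias-correction slope is zero; cannot invert")
  corrected <- switch(method,
    invert = (raw_preds - bc$alpha) / bc$beta,
    residual = raw_preds - (bc$alpha + bc$beta * ages) + ages)
  if (is.null(subject_ids))
    subject_ids <- sprintf("S%04d", seq_along(ages))
  data.frame(subject_id = subject_ids, age = ages, raw_pred = raw_preds,
             corrected_pred = corrected, delta = corrected - ages,
             stringsAsFactors = FALSE)
}

#' Evaluate prediction records
#'
#' @param records a data frame from [apply_bias_correction()] (needs
#'   `corrected_pred` and `age`), n >= 2 with non-constant ages.
#' @return list with `mae` (mean absolute error, years) and `r` (Pearson
#'   correlation of corrected prediction with age; `NA` when the
#'   predictions are constant, in which case r is undefined).
#' @export
evaluate_predictions <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 2L,
            all(c("age", "corrected_pred") %in% names(records)))
  if (sd(records$age) == 0)
    stop_bad_arg("constant ages: correlation undefined")
  mae <- mean(abs(records$corrected_pred - records$age))
  r <- if (sd(records$corrected_pred) == 0) NA_real_
       else unname(cor(records$corrected_pred, records$age))
  list(mae = mae, r = r)
}

#' @importFrom stats cor
NULL
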