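#' Validate a prediction model on a mapped cohort
#'
#' Runs the full external-validation pipeline: computes every retained
#' record's predicted risk with the family engine
#' ([predict_risk()]), then quantifies calibration
#' ([calibration_intercept_slope()], [calibration_bins()]) and
#' discrimination ([roc_and_auc()]). Fully deterministic given its
#' inputs.
#'
#' @param spec A `model_spec`.
#' @param cohort A `mapped_cohort` from [apply_mapping()], or a data
#'   frame holding one column per covariate plus a 0/1 outcome column
#'   `y`.
#' @param horizon Prediction horizon in years (required for the cox,
#'   conditional and lookup families).
#' @param n_bins Number of groups for the calibration table (default 10).
#' @param eps Probability clipping bound for the logit transform.
#' @return An object of class `validation_result` with elements
#'   `predictions` (a `risk_predictions`), `calibration` (intercept,
#'   slope, unrestricted intercept, bin table, `n_bins`, `eps`),
#'   `discrimination` (ROC + AUC), `model_id` and `horizon`.
#' @export
validate_model <- function(spec, cohort, horizon = NULL, n_bins = 10L,
                           eps = 1e-10) {
  dat <- if (inherits(cohort, "mapped_cohort")) cohort$data else cohort
  if (!"y" %in% names(dat))
    pv_mapping_error("cohort data lacks the outcome column 'y'")
  p <- predict_risk(spec, dat, horizon = horizon)
  preds <- risk_predictions(p, dat$y, model_id = spec$model_id,
                            horizon = horizon)
  ab <- calibration_intercept_slope(preds, eps = eps)
  bins <- calibration_bins(preds, n_bins = n_bins)
  calibration <- structure(
    list(intercept = ab$intercept, slope = ab$slope,
         intercept_unrestricted = ab$intercept_unrestricted,
         intercept_se = ab$intercept_se, slope_se = ab$slope_se,
         bins = bins, n_bins = as.integer(n_bins), eps = eps),
    class = "calibration_result")
  structure(list(
    predictions = preds,
    calibration = calibration,
    discrimination = roc_and_auc(preds),
    model_id = spec$model_id,
    horizon = horizon
  ), class = "validation_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> intercept = %.4f, slope = %.4f (unrestricted intercept = %.4f)\n",
              x$intercept, x$slope, x$intercept_unrestricted))
  cat(sprintf("  %d bins; clip eps = %g\n", x$n_bins, x$eps))
  invisible(x)
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> model '%s'%s, n = %d\n",
              x$model_id %||% "?",
              if (!is.null(x$horizon)) sprintf(" at %g years", x$horizon)
              else "",
              length(x$predictions$p)))
  cat(sprintf("  calibration: intercept %.2f, slope %.2f\n",
              x$calibration$intercept, x$calibration$slope))
  cat(sprintf("  discrimination: AUC %.2f\n", x$discrimination$auc))
  invisible(x)
}
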