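# Calibration of predicted risks against observed binary outcomes:
# intercept (calibration-in-the-large, offset fit with slope fixed at 1),
# slope (unrestricted logistic refit on the prediction's logit), and a
# grouped calibration table for plotting observed vs predicted by
# equal-count bins with Wilson 95% confidence intervals.

#' Pair predicted risks with observed outcomes
#'
#' @param p Predicted event probabilities in \[0, 1\].
#' @param y Observed binary outcomes, 1 = event, 0 = non-event.
#' @param model_id Optional model identifier carried through to reports.
#' @param horizon Optional prediction horizon (years).
#' @return An object of class `risk_predictions`.
#' @export
risk_predictions <- function(p, y, model_id = NULL, horizon = NULL) {
  if (length(p) != length(y))
    pv_schema_error("p and y must have equal length", "risk_predictions")
  if (length(p) == 0L)
    pv_schema_error("at least one record is required", "risk_predictions")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    pv_schema_error("predicted probabilities must lie in [0, 1]", "p")
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    pv_schema_error("outcomes must be 0/1", "y")
  structure(list(p = as.numeric(p), y = y,
                 model_id = model_id, horizon = horizon),
            class = "risk_predictions")
}

as_risk_predictions <- function(x) {
  if (inherits(x, "risk_predictions")) return(x)
  risk_predictions(x$p, x$y, x$model_id, x$horizon)
}

check_both_classes <- function(y) {
  if (all(y == 1L) || all(y == 0L))
    pv_degenerate_error(
      "outcome has a single class; calibration slope and AUC are undefined")
}

# Newton polish: glm stops on a relative deviance criterion, which at
# large n can leave an absolute score norm above the contract's 1e-8;
# a few extra Fisher-scoring steps close the gap.
newton_polish <- function(X, y, beta, offset = 0, tol = 1e-8,
                          maxit = 25L) {
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- plogis(eta)
    g <- drop(crossprod(X, y - mu))
    if (sqrt(sum(g^2)) < tol) return(list(beta = beta, score = g))
    H <- crossprod(X * (mu * (1 - mu)), X)
    beta <- beta + solve(H, g)
  }
  eta <- drop(X %*% beta) + offset
  list(beta = beta, score = drop(crossprod(X, y - plogis(eta))))
}

#' Calibration intercept and slope
#'
#' Let `l = logit(p)` be the logit of the predicted risks (clipped to
#' `[eps, 1 - eps]` first). The calibration slope `b` is the coefficient
#' on `l` in a maximum-likelihood logistic regression of the observed
#' outcome on `l`; the calibration intercept `a`
#' (calibration-in-the-large) is the intercept of a second logistic fit
#' in which `l` enters as a fixed offset (slope constrained to 1). A
#' perfectly calibrated model has `a = 0`, `b = 1`. The intercept of the
#' unrestricted fit is also returned (`intercept_unrestricted`) since the
#' validation literature uses both conventions.
#'
#' Both fits are iteratively reweighted least squares (Fisher scoring)
#' fits; convergence is verified by requiring the score norm to fall
#' below `1e-8`, otherwise a `pv_fit_error` is raised.
#'
#' @param preds A [risk_predictions()] object (both outcome classes must
#'   be present).
#' @param eps Clipping bound applied to `p` before the logit transform.
#' @return A list with `intercept`, `slope`, `intercept_unrestricted`
#'   and `eps`.
#' @export
calibration_intercept_slope <- function(preds, eps = 1e-10) {
  preds <- as_risk_predictions(preds)
  y <- preds$y
  check_both_classes(y)
  lp <- qlogis(pmin(pmax(preds$p, eps), 1 - eps))

  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  slope_fit <- glm(y ~ lp, family = binomial(), control = ctrl)
  offset_fit <- glm(y ~ 1, family = binomial(), offset = lp, control = ctrl)
  if (!slope_fit$converged || !offset_fit$converged)
    pv_fit_error(sprintf(
      "logistic recalibration fit did not converge (slope fit: %d iterations, offset fit: %d)",
      slope_fit$iter, offset_fit$iter))
  pol1 <- newton_polish(cbind(1, lp), y, unname(coef(slope_fit)))
  pol2 <- newton_polish(matrix(1, length(y)), y,
                        unname(coef(offset_fit)), offset = lp)
  g1 <- sqrt(sum(pol1$score^2))
  g2 <- sqrt(sum(pol2$score^2))
  if (g1 > 1e-8 || g2 > 1e-8)
    pv_fit_error(sprintf(
      "recalibration fit score norm above tolerance (%.3g, %.3g)", g1, g2))

  list(intercept = pol2$beta[1],
       slope = pol1$beta[2],
       intercept_unrestricted = pol1$beta[1],
       intercept_se = unname(sqrt(stats::vcov(offset_fit)[1, 1])),
       intercept_unrestricted_se = unname(sqrt(stats::vcov(slope_fit)[1, 1])),
       slope_se = unname(sqrt(stats::vcov(slope_fit)[2, 2])),
       eps = eps)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of events.
#' @param n Number of trials (n >= 1).
#' @param conf Confidence level, default 0.95.
#' @return A two-column matrix (`low`, `high`); always contains `k / n`
#'   and lies within \[0, 1\].
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  cbind(low = pmax(0, center - half), high = pmin(1, center + half))
}

#' Grouped calibration table
#'
#' Sorts records by predicted risk (stable sort: ties keep input order)
#' and splits them into `n_bins` contiguous equal-count groups of size
#' `floor(n / n_bins)`, the first `n %% n_bins` groups one record larger.
#' Per bin it reports the record count, mean predicted risk, observed
#' event proportion, and its 95% Wilson score interval — the data behind
#' a decile-grouped calibration plot compared against the perfect
#' prediction line `y = x`.
#'
#' @param preds A [risk_predictions()] object.
#' @param n_bins Number of groups (default 10, i.e. deciles).
#' @return Data frame with columns `bin`, `n`, `mean_predicted`,
#'   `observed`, `ci_low`, `ci_high`.
#' @export
calibration_bins <- function(preds, n_bins = 10L) {
  preds <- as_risk_predictions(preds)
  n <- length(preds$p)
  if (n_bins < 2L)
    pv_bin_error("at least two bins are required")
  if (n < n_bins)
    pv_bin_error(sprintf("cannot form %d bins from %d records", n_bins, n))
  ord <- order(preds$p)  # radix sort: stable, ties keep input order
  sizes <- rep(n %/% n_bins, n_bins)
  if (n %% n_bins > 0) sizes[seq_len(n %% n_bins)] <- sizes[1] + 1L
  bin <- rep(seq_len(n_bins), sizes)
  p_s <- preds$p[ord]
  y_s <- preds$y[ord]
  k <- as.numeric(tapply(y_s, bin, sum))
  nb <- as.numeric(tapply(y_s, bin, length))
  ci <- wilson_ci(k, nb)
  data.frame(bin = seq_len(n_bins), n = nb,
             mean_predicted = as.numeric(tapply(p_s, bin, mean)),
             observed = k / nb,
             ci_low = ci[, "low"], ci_high = ci[, "high"])
}
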