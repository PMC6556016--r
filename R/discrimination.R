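# Discrimination: ROC curve and AUC. The AUC is computed by the
# Mann-Whitney concordance formula (ties count 0.5), which equals the
# trapezoidal area under the empirical ROC curve.

#' ROC curve and area under the curve
#'
#' The ROC curve plots sensitivity against 1 - specificity at every
#' distinct predicted value taken as a classification threshold
#' (predict an event when `p >= threshold`), in descending threshold
#' order, with an `Inf` sentinel so the curve starts at (0, 0) and ends
#' at (1, 1). The AUC is the probability that a randomly chosen event
#' receives a higher predicted risk than a randomly chosen non-event,
#' ties counted one half: 1.0 is perfect discrimination, 0.5 is a
#' coin-flip predictor.
#'
#' @param preds A [risk_predictions()] object (both outcome classes must
#'   be present).
#' @return An object of class `discrimination_result`: `roc` (data frame
#'   with `threshold`, `sensitivity`, `fpr` = 1 - specificity) and
#'   `auc`.
#' @export
roc_and_auc <- function(preds) {
  preds <- as_risk_predictions(preds)
  p <- preds$p
  y <- preds$y
  check_both_classes(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)

  ord <- order(p, decreasing = TRUE)
  p_s <- p[ord]
  y_s <- y[ord]
  # one ROC point per distinct predicted value: cumulative counts at the
  # last record of each tie group
  last <- which(c(p_s[-1] != p_s[-length(p_s)], TRUE))
  tp <- cumsum(y_s)[last]
  fp <- cumsum(1L - y_s)[last]
  roc <- data.frame(threshold = c(Inf, p_s[last]),
                    sensitivity = c(0, tp / n1),
                    fpr = c(0, fp / n0))

  # Mann-Whitney via midranks: equals the trapezoidal area under `roc`
  r <- rank(p, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  structure(list(roc = roc, auc = auc, n_events = n1, n_nonevents = n0),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("<discrimination_result> AUC = %.4f (%d events, %d non-events, %d ROC points)\n",
              x$auc, x$n_events, x$n_nonevents, nrow(x$roc)))
  invisible(x)
}
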