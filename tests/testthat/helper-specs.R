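# Small hand-buildable specs used across tests.

tiny_logistic_spec <- function(intercept = 0) {
  model_spec(
    model_id = "tiny_logit", family = "logistic", horizons = 1,
    covariates = list(
      covariate_def("x", "continuous", center = 50,
                    dev_summary = list(mean = 52, sd = 10)),
      covariate_def("g", "categorical", levels = c("A", "B"),
                    reference_level = "A",
                    unknown_weights = c(A = 0.5, B = 0.5))),
    intercept = intercept,
    coefficients = list(x = 0.2, g = c(B = 1)))
}

tiny_cox_spec <- function(s0 = c(0.9, 0.8)) {
  model_spec(
    model_id = "tiny_cox", family = "cox",
    covariates = list(
      covariate_def("x", "continuous"),
      covariate_def("g", "categorical", levels = c("A", "B"),
                    reference_level = "A")),
    coefficients = list(x = 0.1, g = c(B = 0.5)),
    baseline_survival = data.frame(time = c(5, 10), survival = s0))
}

tiny_conditional_spec <- function(intercepts = c(-2, -2.5)) {
  model_spec(
    model_id = "tiny_cond", family = "conditional_logistic",
    covariates = list(
      covariate_def("x", "continuous")),
    periods = lapply(intercepts, function(b0)
      list(intercept = b0, coefficients = list(x = 0.3))))
}

tiny_lookup_spec <- function() {
  model_spec(
    model_id = "tiny_lookup", family = "lookup",
    covariates = list(
      covariate_def("age", "continuous"),
      covariate_def("g", "categorical", levels = c("A", "B"),
                    reference_level = "A")),
    discretization = list(
      age = list(breaks = c(0, 50, 120), labels = c("young", "old"))),
    lookup_table = data.frame(
      key = c("young|A", "young|B", "old|A", "old|B"),
      horizon = 5,
      probability = c(0.1, 0.2, 0.3, 0.4)))
}

# A cohort whose empirical event fraction matches p exactly at every
# distinct predicted value, so the recalibration MLE is exactly (0, 1).
exactly_calibrated_preds <- function() {
  p <- c(rep(0.2, 10), rep(0.5, 10), rep(0.8, 10))
  y <- c(rep(1, 2), rep(0, 8), rep(1, 5), rep(0, 5), rep(1, 8), rep(0, 2))
  risk_predictions(p, y, model_id = "exact")
}
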