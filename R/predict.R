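# Prediction engines: pure functions of (spec, covariate values).
# Records are rows of a data frame with one column per model covariate;
# categorical columns hold level labels as character, continuous columns
# are numeric. NA marks an unknown value (resolved via unknown_weights
# for categorical covariates, via the development-cohort mean for
# continuous ones).

normalize_records <- function(spec, data) {
  if (!is.data.frame(data))
    data <- as.data.frame(data, stringsAsFactors = FALSE, optional = TRUE)
  missing_cols <- setdiff(names(spec$covariates), names(data))
  if (length(missing_cols))
    pv_mapping_error(sprintf("records lack covariate column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  for (cd in spec$covariates) {
    v <- data[[cd$name]]
    if (cd$kind == "categorical") {
      v <- as.character(v)
      bad <- !is.na(v) & !(v %in% cd$levels)
      if (any(bad))
        pv_mapping_error(sprintf(
          "covariate '%s': value '%s' is not a declared level (row %d)",
          cd$name, v[which(bad)[1]], which(bad)[1]))
    } else {
      if (!is.numeric(v)) {
        suppressWarnings(vn <- as.numeric(v))
        if (any(is.na(vn) & !is.na(v)))
          pv_mapping_error(sprintf(
            "covariate '%s': non-numeric value for continuous covariate",
            cd$name))
        v <- vn
      }
    }
    data[[cd$name]] <- v
  }
  data
}

# Per-covariate contribution to the linear predictor under a coefficient
# map; reference levels contribute 0, unknown values the weighted average
# of their level coefficients.
covariate_contribution <- function(cd, values, coefs) {
  b <- coefs[[cd$name]]
  if (cd$kind == "continuous") {
    beta <- if (is.null(b)) 0 else b
    center <- cd$center %||% 0
    out <- beta * (values - center)
    if (anyNA(values)) {
      if (is.null(cd$dev_summary$mean))
        pv_unknown_error(sprintf(
          "covariate '%s' is unknown but carries no development mean",
          cd$name))
      out[is.na(values)] <- beta * (cd$dev_summary$mean - center)
    }
    out
  } else {
    betas <- setNames(numeric(length(cd$levels)), cd$levels)
    if (!is.null(b)) betas[names(b)] <- b
    out <- unname(betas[values])
    if (anyNA(values)) {
      if (is.null(cd$unknown_weights))
        pv_unknown_error(sprintf(
          "covariate '%s' is unknown but carries no unknown_weights",
          cd$name))
      w <- cd$unknown_weights
      out[is.na(values)] <- sum(w * betas[names(w)])
    }
    out
  }
}

#' Linear predictor of a regression-family model
#'
#' Computes `LP = sum_j contribution_j` over the model's covariates:
#' a categorical non-reference level contributes its coefficient, the
#' reference level 0, a continuous value `beta * (x - center)`, and an
#' unknown value (`NA`) the weighted average of level coefficients under
#' the covariate's `unknown_weights` (categorical) or the contribution of
#' the development-cohort mean (continuous). The intercept is included
#' for the logistic families and excluded for Cox models.
#'
#' @param spec A `model_spec` of family `logistic`,
#'   `conditional_logistic` or `cox`.
#' @param data Data frame of records (one column per covariate), or a
#'   named list for a single record.
#' @param period Follow-up year `k` selecting the period-specific
#'   coefficients; required iff the family is `conditional_logistic`.
#' @return Numeric vector of linear predictors, one per record.
#' @export
linear_predictor <- function(spec, data, period = NULL) {
  if (spec$family == "lookup")
    pv_schema_error("lookup models have no linear predictor", "family")
  if (spec$family == "conditional_logistic") {
    if (is.null(period))
      pv_horizon_error("conditional_logistic requires a period")
    K <- length(spec$periods)
    if (period < 1 || period > K)
      pv_horizon_error(sprintf("period %d outside 1..%d", period, K))
    coefs <- spec$periods[[period]]$coefficients
    intercept <- spec$periods[[period]]$intercept
  } else {
    if (!is.null(period))
      pv_horizon_error(sprintf("family '%s' takes no period", spec$family))
    coefs <- spec$coefficients
    intercept <- if (spec$family == "logistic") spec$intercept else 0
  }
  data <- normalize_records(spec, data)
  lp <- rep(intercept, nrow(data))
  for (cd in spec$covariates)
    lp <- lp + covariate_contribution(cd, data[[cd$name]], coefs)
  lp
}

#' Predicted probability from a logistic model
#'
#' @inheritParams linear_predictor
#' @return Event probabilities `1 / (1 + exp(-LP))`, strictly in (0, 1).
#' @export
predict_logistic <- function(spec, data) {
  if (spec$family != "logistic")
    pv_schema_error(sprintf("predict_logistic on family '%s'", spec$family),
                    "family")
  plogis(linear_predictor(spec, data))
}

match_horizon <- function(times, horizon, what) {
  i <- which(abs(times - horizon) < 1e-9)
  if (length(i) != 1L)
    pv_horizon_error(sprintf(
      "horizon %g not in %s (available: %s); no interpolation is performed",
      horizon, what, paste(times, collapse = ", ")))
  i
}

#' Event risk by a horizon from a Cox model with baseline survival
#'
#' `risk(t) = 1 - S0(t)^exp(LP)`, with `S0(t)` looked up exactly in the
#' spec's baseline survival table (no interpolation between horizons).
#'
#' @inheritParams linear_predictor
#' @param horizon Prediction horizon in years; must equal one of the
#'   tabulated baseline-survival times.
#' @return Event probabilities in \[0, 1).
#' @export
predict_cox <- function(spec, data, horizon) {
  if (spec$family != "cox")
    pv_schema_error(sprintf("predict_cox on family '%s'", spec$family),
                    "family")
  i <- match_horizon(spec$baseline_survival$time, horizon,
                     "the baseline survival table")
  s0 <- spec$baseline_survival$survival[i]
  1 - s0 ^ exp(linear_predictor(spec, data))
}

#' Annual conditional risks of a conditional (period-wise) logistic model
#'
#' @inheritParams linear_predictor
#' @return An `n x K` matrix whose `[i, k]` entry is the conditional risk
#'   of an event in year `k` given event-free survival through year
#'   `k - 1`, for record `i`.
#' @export
conditional_annual_risks <- function(spec, data) {
  if (spec$family != "conditional_logistic")
    pv_schema_error(sprintf("conditional risks on family '%s'", spec$family),
                    "family")
  K <- length(spec$periods)
  vapply(seq_len(K),
         function(k) plogis(linear_predictor(spec, data, period = k)),
         numeric(NROW(normalize_records(spec, data))))
}

#' Cumulative risk through a follow-up year from a conditional model
#'
#' Cumulative risk through year `t` is `1 - prod_{k<=t} (1 - r_k)` over
#' the annual conditional risks `r_k`. The full matrix of annual risks
#' (all `K` periods) is attached as attribute `"annual_risks"`.
#'
#' @inheritParams linear_predictor
#' @param through_year Last follow-up year included, `1 <= t <= K`.
#' @return Cumulative event probabilities.
#' @export
predict_conditional <- function(spec, data, through_year) {
  K <- length(spec$periods)
  if (through_year < 1 || through_year > K)
    pv_horizon_error(sprintf("through_year %g outside supported range 1..%d",
                             through_year, K))
  r <- conditional_annual_risks(spec, data)
  if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
  cum <- 1 - apply(1 - r[, seq_len(through_year), drop = FALSE], 1L, prod)
  attr(cum, "annual_risks") <- r
  cum
}

# Discretize each covariate of a lookup model and form the exact profile
# key (labels joined by "|" in covariate order). Continuous covariates
# use half-open bins [lo, hi).
profile_keys <- function(spec, data) {
  labels <- lapply(spec$covariates, function(cd) {
    v <- data[[cd$name]]
    if (cd$kind == "categorical") {
      if (anyNA(v))
        pv_unknown_error(sprintf(
          "lookup models cannot score unknown values (covariate '%s')",
          cd$name))
      v
    } else {
      d <- spec$discretization[[cd$name]]
      if (anyNA(v))
        pv_unknown_error(sprintf(
          "lookup models cannot score unknown values (covariate '%s')",
          cd$name))
      idx <- findInterval(v, d$breaks, rightmost.closed = FALSE,
                          left.open = FALSE)
      out_of_range <- idx < 1L | idx > length(d$labels)
      if (any(out_of_range))
        pv_mapping_error(sprintf(
          "covariate '%s': value %g outside discretization range [%g, %g)",
          cd$name, v[which(out_of_range)[1]], d$breaks[1],
          d$breaks[length(d$breaks)]))
      d$labels[idx]
    }
  })
  do.call(paste, c(labels, sep = "|"))
}

#' Probability from an empirical profile-lookup model
#'
#' Each covariate is discretized according to the spec's rules
#' (continuous values fall into half-open intervals `[lo, hi)`), the
#' labels are joined into a profile key, and the probability for
#' `(key, horizon)` is returned. Matching is exact: an absent profile is
#' an error (`pv_profile_error`), never a nearest-neighbour fallback.
#'
#' @inheritParams predict_cox
#' @return Event probabilities in \[0, 1\].
#' @export
predict_lookup <- function(spec, data, horizon) {
  if (spec$family != "lookup")
    pv_schema_error(sprintf("predict_lookup on family '%s'", spec$family),
                    "family")
  match_horizon(spec$horizons, horizon, "the lookup table horizons")
  data <- normalize_records(spec, data)
  keys <- profile_keys(spec, data)
  lt <- spec$lookup_table
  sub <- lt[abs(lt$horizon - horizon) < 1e-9, , drop = FALSE]
  i <- match(keys, sub$key)
  if (anyNA(i)) {
    miss <- keys[which(is.na(i))[1]]
    pv_profile_error(sprintf(
      "no matching prognostic profile for key '%s' at horizon %g (row %d)",
      miss, horizon, which(is.na(i))[1]))
  }
  sub$probability[i]
}

#' Predicted event risk from any supported model family
#'
#' Dispatches to the family engine: [predict_logistic()] (the horizon is
#' metadata only), [predict_conditional()] (cumulative risk through
#' `horizon` years), [predict_cox()], or [predict_lookup()].
#'
#' @inheritParams predict_cox
#' @return Event probabilities, one per record.
#' @export
predict_risk <- function(spec, data, horizon = NULL) {
  switch(spec$family,
    logistic = predict_logistic(spec, data),
    conditional_logistic = {
      if (is.null(horizon))
        pv_horizon_error("conditional_logistic requires a horizon")
      as.numeric(predict_conditional(spec, data, through_year = horizon))
    },
    cox = {
      if (is.null(horizon)) pv_horizon_error("cox requires a horizon")
      predict_cox(spec, data, horizon)
    },
    lookup = {
      if (is.null(horizon)) pv_horizon_error("lookup requires a horizon")
      predict_lookup(spec, data, horizon)
    })
}
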