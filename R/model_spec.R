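#' Define a model covariate
#'
#' A covariate definition carries everything the prediction engines need
#' to evaluate one term of a model: its measurement kind, the coding of
#' categorical levels, optional weights used to score records whose value
#' is unknown, an optional centering constant for continuous covariates,
#' and an optional summary of the model's development cohort used for
#' baseline comparison.
#'
#' @param name Covariate identifier (must match a key of the model's
#'   coefficient map).
#' @param kind `"continuous"` or `"categorical"`.
#' @param levels Ordered character vector of level labels (categorical
#'   only).
#' @param reference_level Label of the reference level (categorical only);
#'   the reference level carries an implicit coefficient of 0.
#' @param unknown_weights Optional named numeric vector of weights in
#'   \[0, 1\] summing to 1 over (a subset of) `levels`. When a record's
#'   value is unknown, its contribution to the linear predictor is the
#'   weighted average of the level coefficients under these weights.
#' @param center Optional centering constant for continuous covariates;
#'   the contribution is `beta * (x - center)`. Defaults to 0.
#' @param dev_summary Optional development-cohort summary: for categorical
#'   covariates `list(frequencies = c(level = freq, ...))`; for continuous
#'   covariates `list(mean = m, sd = s)`. Used by [compare_baseline()] and
#'   (continuous mean) to impute unknown continuous values.
#' @param transform Reserved for nonlinear covariate transformations;
#'   only `"identity"` (the default, with optional centering) is
#'   currently implemented.
#'
#' @return An object of class `covariate_def`.
#' @export
covariate_def <- function(name, kind = c("continuous", "categorical"),
                          levels = NULL, reference_level = NULL,
                          unknown_weights = NULL, center = NULL,
                          dev_summary = NULL, transform = "identity") {
  kind <- match.arg(kind)
  if (!identical(transform, "identity"))
    pv_schema_error(
      sprintf("transform '%s' is not implemented (only 'identity')",
              transform),
      sprintf("covariates.%s.transform", name))
  cd <- structure(list(
    name = name, kind = kind, levels = levels,
    reference_level = reference_level,
    unknown_weights = unknown_weights,
    center = center, dev_summary = dev_summary,
    transform = transform
  ), class = "covariate_def")
  validate_covariate_def(cd, field = sprintf("covariates.%s", name))
  cd
}

validate_covariate_def <- function(cd, field = "covariate") {
  if (!is.character(cd$name) || length(cd$name) != 1L || !nzchar(cd$name))
    pv_schema_error("covariate name must be a non-empty string", field)
  if (cd$kind == "categorical") {
    if (is.null(cd$levels) || length(cd$levels) < 2L)
      pv_schema_error("categorical covariate needs at least two levels",
                      paste0(field, ".levels"))
    if (anyDuplicated(cd$levels))
      pv_schema_error("duplicated level labels", paste0(field, ".levels"))
    if (is.null(cd$reference_level) ||
        !(cd$reference_level %in% cd$levels))
      pv_schema_error("reference_level must be one of the declared levels",
                      paste0(field, ".reference_level"))
    if (!is.null(cd$unknown_weights)) {
      w <- cd$unknown_weights
      if (is.null(names(w)) || !all(names(w) %in% cd$levels))
        pv_schema_error("unknown_weights keys must be declared levels",
                        paste0(field, ".unknown_weights"))
      if (any(w < 0) || any(w > 1))
        pv_schema_error("unknown_weights must lie in [0, 1]",
                        paste0(field, ".unknown_weights"))
      if (abs(sum(w) - 1) > 1e-9)
        pv_schema_error(
          sprintf("unknown_weights must sum to 1 (got %.12g)", sum(w)),
          paste0(field, ".unknown_weights"))
    }
    if (!is.null(cd$center))
      pv_schema_error("categorical covariate cannot carry a center",
                      paste0(field, ".center"))
    if (!is.null(cd$dev_summary)) {
      fr <- cd$dev_summary$frequencies
      if (is.null(fr) || is.null(names(fr)) || !all(names(fr) %in% cd$levels))
        pv_schema_error("dev_summary$frequencies must be named over levels",
                        paste0(field, ".dev_summary"))
      if (abs(sum(fr) - 1) > 1e-9)
        pv_schema_error("dev_summary frequencies must sum to 1",
                        paste0(field, ".dev_summary"))
    }
  } else {
    if (!is.null(cd$levels) || !is.null(cd$reference_level) ||
        !is.null(cd$unknown_weights))
      pv_schema_error(
        "continuous covariate cannot carry levels/reference/unknown_weights",
        field)
    if (!is.null(cd$center) &&
        (!is.numeric(cd$center) || length(cd$center) != 1L))
      pv_schema_error("center must be a single number",
                      paste0(field, ".center"))
    if (!is.null(cd$dev_summary)) {
      ds <- cd$dev_summary
      if (is.null(ds$mean) || is.null(ds$sd) || ds$sd <= 0)
        pv_schema_error("continuous dev_summary needs mean and sd > 0",
                        paste0(field, ".dev_summary"))
    }
  }
  invisible(cd)
}

#' Construct a prediction-model specification
#'
#' A `model_spec` is a self-contained, serializable description of a
#' published prediction model, sufficient to compute individual risks.
#' Four families are supported:
#'
#' * `logistic` — intercept + coefficients; risk is the inverse logit of
#'   the linear predictor.
#' * `conditional_logistic` — one logistic model per follow-up year
#'   (periods `1..K`); the cumulative risk through year `t` is
#'   `1 - prod(1 - r_k)` over the annual conditional risks `r_k`.
#' * `cox` — coefficients plus a baseline survival table `S0(t)`; the
#'   risk of an event by horizon `t` is `1 - S0(t)^exp(LP)`.
#' * `lookup` — an empirical profile-to-probability table with
#'   per-covariate discretization rules (half-open intervals for
#'   continuous covariates); matching is exact.
#'
#' @param model_id Identifier string.
#' @param family One of `"logistic"`, `"conditional_logistic"`, `"cox"`,
#'   `"lookup"`.
#' @param covariates List of [covariate_def()] objects (order matters: it
#'   defines the profile-key order for lookup models).
#' @param coefficients Named list: continuous covariate -> single beta;
#'   categorical covariate -> named numeric vector of betas over
#'   non-reference levels (logistic and cox families).
#' @param intercept Model intercept (logistic family only).
#' @param periods For `conditional_logistic`: list of
#'   `list(intercept =, coefficients =)` per follow-up year `k = 1..K`.
#' @param baseline_survival For `cox`: data frame with columns `time`
#'   (years) and `survival` (`S0(t)` in (0, 1\]), non-increasing in time.
#' @param discretization For `lookup`: named list per continuous covariate
#'   of `list(breaks =, labels =)` defining half-open bins `[lo, hi)`;
#'   categorical covariates use their level labels directly.
#' @param lookup_table For `lookup`: data frame with columns `key`
#'   (profile labels joined by `"|"` in covariate order), `horizon`, and
#'   `probability`.
#' @param outcome_label Human-readable outcome description.
#' @param horizons Numeric vector of supported prediction horizons in
#'   years. Defaults per family (cox: baseline-survival times;
#'   conditional: `1..K`).
#'
#' @return A validated object of class `model_spec`.
#' @seealso [load_model_spec()], [write_model_spec()], [predict_risk()]
#' @export
model_spec <- function(model_id, family, covariates,
                       coefficients = NULL, intercept = NULL,
                       periods = NULL, baseline_survival = NULL,
                       discretization = NULL, lookup_table = NULL,
                       outcome_label = "", horizons = NULL) {
  names(covariates) <- vapply(covariates, function(cd) cd$name, character(1))
  if (is.null(horizons)) {
    horizons <- switch(family,
      cox = baseline_survival$time,
      conditional_logistic = seq_along(periods),
      lookup = sort(unique(lookup_table$horizon)),
      logistic = 1,  # a plain logistic model has one implicit horizon
      NULL)
  }
  spec <- structure(list(
    spec_version = "1",
    model_id = model_id, family = family,
    covariates = covariates,
    coefficients = coefficients, intercept = intercept,
    periods = periods, baseline_survival = baseline_survival,
    discretization = discretization, lookup_table = lookup_table,
    outcome_label = outcome_label, horizons = horizons
  ), class = "model_spec")
  validate_model_spec(spec)
  spec
}

FAMILIES <- c("logistic", "conditional_logistic", "cox", "lookup")

validate_coef_map <- function(coefs, covariates, field) {
  if (is.null(coefs))
    pv_schema_error("coefficient map is required", field)
  extra <- setdiff(names(coefs), names(covariates))
  if (length(extra))
    pv_schema_error(sprintf("coefficients for undeclared covariates: %s",
                            paste(extra, collapse = ", ")), field)
  for (nm in names(coefs)) {
    cd <- covariates[[nm]]
    b <- coefs[[nm]]
    f <- paste0(field, ".", nm)
    if (cd$kind == "continuous") {
      if (!is.numeric(b) || length(b) != 1L)
        pv_schema_error("continuous coefficient must be one number", f)
    } else {
      nonref <- setdiff(cd$levels, cd$reference_level)
      if (is.null(names(b)) || !all(names(b) %in% nonref))
        pv_schema_error(
          "categorical coefficients must be named over non-reference levels",
          f)
    }
  }
  invisible(coefs)
}

#' Validate a model specification
#'
#' Checks all structural invariants of a `model_spec`; violations raise a
#' classed `pv_schema_error` naming the offending field path.
#'
#' @param spec A `model_spec`.
#' @return The spec, invisibly, if valid.
#' @export
validate_model_spec <- function(spec) {
  if (!is.character(spec$model_id) || !nzchar(spec$model_id))
    pv_schema_error("model_id must be a non-empty string", "model_id")
  if (!spec$family %in% FAMILIES)
    pv_schema_error(sprintf("family must be one of %s",
                            paste(FAMILIES, collapse = ", ")), "family")
  if (length(spec$covariates) < 1L)
    pv_schema_error("at least one covariate is required", "covariates")
  for (cd in spec$covariates)
    validate_covariate_def(cd, sprintf("covariates.%s", cd$name))

  fam <- spec$family
  forbid <- function(x, nm, why) {
    if (!is.null(x))
      pv_schema_error(sprintf("%s is not used by family '%s'%s", nm, fam, why),
                      nm)
  }
  if (fam == "logistic") {
    if (!is.numeric(spec$intercept) || length(spec$intercept) != 1L)
      pv_schema_error("logistic family requires a single intercept",
                      "intercept")
    validate_coef_map(spec$coefficients, spec$covariates, "coefficients")
    forbid(spec$periods, "periods", "")
    forbid(spec$baseline_survival, "baseline_survival", "")
    forbid(spec$lookup_table, "lookup_table", "")
  } else if (fam == "conditional_logistic") {
    if (is.null(spec$periods) || length(spec$periods) < 1L)
      pv_schema_error("conditional_logistic requires >= 1 period", "periods")
    for (k in seq_along(spec$periods)) {
      per <- spec$periods[[k]]
      f <- sprintf("periods[%d]", k)
      if (!is.numeric(per$intercept) || length(per$intercept) != 1L)
        pv_schema_error("each period requires an intercept",
                        paste0(f, ".intercept"))
      validate_coef_map(per$coefficients, spec$covariates,
                        paste0(f, ".coefficients"))
    }
    forbid(spec$coefficients, "coefficients",
           " (use per-period coefficients)")
    forbid(spec$intercept, "intercept", " (use per-period intercepts)")
    forbid(spec$baseline_survival, "baseline_survival", "")
    forbid(spec$lookup_table, "lookup_table", "")
  } else if (fam == "cox") {
    validate_coef_map(spec$coefficients, spec$covariates, "coefficients")
    bs <- spec$baseline_survival
    if (is.null(bs) || !all(c("time", "survival") %in% names(bs)) ||
        nrow(bs) < 1L)
      pv_schema_error("cox requires a baseline_survival table (time, survival)",
                      "baseline_survival")
    if (is.unsorted(bs$time, strictly = TRUE))
      pv_schema_error("baseline_survival times must be strictly increasing",
                      "baseline_survival.time")
    if (any(bs$survival <= 0) || any(bs$survival > 1))
      pv_schema_error("baseline survival must lie in (0, 1]",
                      "baseline_survival.survival")
    if (any(diff(bs$survival) > 0))
      pv_schema_error("baseline survival must be non-increasing in time",
                      "baseline_survival.survival")
    forbid(spec$intercept, "intercept",
           " (the baseline survival plays that role)")
    forbid(spec$periods, "periods", "")
    forbid(spec$lookup_table, "lookup_table", "")
  } else { # lookup
    lt <- spec$lookup_table
    if (is.null(lt) ||
        !all(c("key", "horizon", "probability") %in% names(lt)) ||
        nrow(lt) < 1L)
      pv_schema_error(
        "lookup requires a lookup_table (key, horizon, probability)",
        "lookup_table")
    if (any(lt$probability < 0) || any(lt$probability > 1))
      pv_schema_error("lookup probabilities must lie in [0, 1]",
                      "lookup_table.probability")
    if (anyDuplicated(paste(lt$key, lt$horizon)))
      pv_schema_error("duplicated (key, horizon) entries",
                      "lookup_table.key")
    for (cd in spec$covariates) {
      if (cd$kind == "continuous") {
        d <- spec$discretization[[cd$name]]
        f <- sprintf("discretization.%s", cd$name)
        if (is.null(d) || is.null(d$breaks) || is.null(d$labels))
          pv_schema_error(
            "continuous covariates of a lookup model need breaks and labels",
            f)
        if (is.unsorted(d$breaks, strictly = TRUE))
          pv_schema_error("breaks must be strictly increasing",
                          paste0(f, ".breaks"))
        if (length(d$labels) != length(d$breaks) - 1L)
          pv_schema_error("need one label per interval",
                          paste0(f, ".labels"))
      }
    }
    forbid(spec$coefficients, "coefficients", "")
    forbid(spec$intercept, "intercept", "")
    forbid(spec$periods, "periods", "")
    forbid(spec$baseline_survival, "baseline_survival", "")
  }
  if (!is.numeric(spec$horizons) || length(spec$horizons) < 1L)
    pv_schema_error("at least one prediction horizon is required", "horizons")
  invisible(spec)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec '%s'> family: %s\n", x$model_id, x$family))
  cat(sprintf("  outcome: %s\n",
              if (nzchar(x$outcome_label)) x$outcome_label else "(unlabelled)"))
  cat(sprintf("  horizons (years): %s\n", paste(x$horizons, collapse = ", ")))
  cat(sprintf("  covariates (%d):\n", length(x$covariates)))
  for (cd in x$covariates) {
    if (cd$kind == "categorical") {
      cat(sprintf("    %s: categorical [%s], ref=%s%s\n", cd$name,
                  paste(cd$levels, collapse = ", "), cd$reference_level,
                  if (!is.null(cd$unknown_weights)) ", unknown-capable" else ""))
    } else {
      cat(sprintf("    %s: continuous (center=%g)%s\n", cd$name,
                  cd$center %||% 0,
                  if (!is.null(cd$dev_summary)) ", unknown-capable" else ""))
    }
  }
  if (x$family == "conditional_logistic")
    cat(sprintf("  periods: K = %d\n", length(x$periods)))
  if (x$family == "cox")
    cat(sprintf("  baseline survival: S0(%s) = %s\n",
                paste(x$baseline_survival$time, collapse = ","),
                paste(signif(x$baseline_survival$survival, 4),
                      collapse = ",")))
  if (x$family == "lookup")
    cat(sprintf("  lookup table: %d (profile, horizon) entries\n",
                nrow(x$lookup_table)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- JSON serialization ----------------------------------------------------

spec_to_list <- function(spec) {
  covs <- lapply(spec$covariates, function(cd) {
    out <- list(name = cd$name, kind = cd$kind)
    if (cd$kind == "categorical") {
      out$levels <- as.list(cd$levels)
      out$reference_level <- cd$reference_level
      if (!is.null(cd$unknown_weights))
        out$unknown_weights <- as.list(cd$unknown_weights)
      if (!is.null(cd$dev_summary))
        out$dev_summary <- list(
          frequencies = as.list(cd$dev_summary$frequencies))
    } else {
      if (!is.null(cd$center)) out$center <- cd$center
      if (!is.null(cd$dev_summary))
        out$dev_summary <- list(mean = cd$dev_summary$mean,
                                sd = cd$dev_summary$sd)
    }
    out
  })
  coef_list <- function(coefs) {
    lapply(coefs, function(b) if (length(b) > 1L || !is.null(names(b)))
      as.list(b) else b)
  }
  out <- list(spec_version = spec$spec_version,
              model_id = spec$model_id,
              family = spec$family,
              outcome_label = spec$outcome_label,
              horizons = as.list(spec$horizons),
              covariates = unname(covs))
  if (!is.null(spec$intercept)) out$intercept <- spec$intercept
  if (!is.null(spec$coefficients))
    out$coefficients <- coef_list(spec$coefficients)
  if (!is.null(spec$periods))
    out$periods <- lapply(spec$periods, function(p)
      list(intercept = p$intercept, coefficients = coef_list(p$coefficients)))
  if (!is.null(spec$baseline_survival))
    out$baseline_survival <- lapply(seq_len(nrow(spec$baseline_survival)),
      function(i) list(time = spec$baseline_survival$time[i],
                       survival = spec$baseline_survival$survival[i]))
  if (!is.null(spec$discretization))
    out$discretization <- lapply(spec$discretization, function(d)
      list(breaks = as.list(d$breaks), labels = as.list(d$labels)))
  if (!is.null(spec$lookup_table))
    out$lookup_table <- lapply(seq_len(nrow(spec$lookup_table)),
      function(i) list(key = spec$lookup_table$key[i],
                       horizon = spec$lookup_table$horizon[i],
                       probability = spec$lookup_table$probability[i]))
  out
}

list_to_spec <- function(x, where = "model spec") {
  need <- c("spec_version", "model_id", "family", "covariates")
  miss <- setdiff(need, names(x))
  if (length(miss))
    pv_schema_error(sprintf("missing required field(s): %s",
                            paste(miss, collapse = ", ")), where)
  if (!identical(as.character(x$spec_version), "1"))
    pv_schema_error(sprintf("unsupported spec_version '%s'", x$spec_version),
                    "spec_version")
  num_vec <- function(v) vapply(v, as.numeric, numeric(1))
  named_num <- function(v) {
    out <- vapply(v, as.numeric, numeric(1))
    names(out) <- names(v)
    out
  }
  covs <- lapply(x$covariates, function(c0) {
    ds <- NULL
    if (!is.null(c0$dev_summary)) {
      ds <- if (identical(c0$kind, "categorical"))
        list(frequencies = named_num(c0$dev_summary$frequencies))
      else list(mean = as.numeric(c0$dev_summary$mean),
                sd = as.numeric(c0$dev_summary$sd))
    }
    covariate_def(
      name = c0$name, kind = c0$kind,
      levels = if (!is.null(c0$levels)) unlist(c0$levels),
      reference_level = c0$reference_level,
      unknown_weights = if (!is.null(c0$unknown_weights))
        named_num(c0$unknown_weights),
      center = if (!is.null(c0$center)) as.numeric(c0$center),
      dev_summary = ds)
  })
  parse_coefs <- function(cl) {
    if (is.null(cl)) return(NULL)
    lapply(cl, function(b) if (is.list(b)) named_num(b) else as.numeric(b))
  }
  bs <- NULL
  if (!is.null(x$baseline_survival))
    bs <- data.frame(
      time = vapply(x$baseline_survival, function(r) as.numeric(r$time),
                    numeric(1)),
      survival = vapply(x$baseline_survival,
                        function(r) as.numeric(r$survival), numeric(1)))
  lt <- NULL
  if (!is.null(x$lookup_table))
    lt <- data.frame(
      key = vapply(x$lookup_table, function(r) as.character(r$key),
                   character(1)),
      horizon = vapply(x$lookup_table, function(r) as.numeric(r$horizon),
                       numeric(1)),
      probability = vapply(x$lookup_table,
                           function(r) as.numeric(r$probability), numeric(1)),
      stringsAsFactors = FALSE)
  disc <- NULL
  if (!is.null(x$discretization))
    disc <- lapply(x$discretization, function(d)
      list(breaks = num_vec(d$breaks),
           labels = vapply(d$labels, as.character, character(1))))
  model_spec(
    model_id = x$model_id, family = x$family, covariates = covs,
    coefficients = parse_coefs(x$coefficients),
    intercept = if (!is.null(x$intercept)) as.numeric(x$intercept),
    periods = if (!is.null(x$periods)) lapply(x$periods, function(p)
      list(intercept = as.numeric(p$intercept),
           coefficients = parse_coefs(p$coefficients))),
    baseline_survival = bs, discretization = disc, lookup_table = lt,
    outcome_label = x$outcome_label %||% "",
    horizons = if (!is.null(x$horizons)) num_vec(x$horizons))
}

#' Load a model specification from JSON
#'
#' Parses and validates a JSON model specification (`spec_version` 1).
#' Parse failures raise `pv_parse_error`; invariant violations raise
#' `pv_schema_error` naming the offending field path.
#'
#' @param path Path to a JSON file written by [write_model_spec()] (or by
#'   hand to the same schema).
#' @return A validated `model_spec`.
#' @export
load_model_spec <- function(path) {
  if (!file.exists(path))
    pv_io_error(sprintf("model spec file not found: %s", path))
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e)
                  pv_parse_error(sprintf("cannot parse %s as JSON: %s",
                                         path, conditionMessage(e))))
  list_to_spec(x, where = path)
}

#' Write a model specification to JSON
#'
#' The writer is canonical: writing the same spec twice produces
#' byte-identical files, and `load_model_spec()` of the output returns an
#' equal spec (serialize/parse fixed point).
#'
#' @param spec A `model_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  validate_model_spec(spec)
  json <- jsonlite::toJSON(spec_to_list(spec), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
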