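# Synthetic cohorts with known truth. The generator draws covariates
# i.i.d. from per-covariate recipes, computes each record's model risk,
# applies a controlled miscalibration on the logit scale
# (logit p_outcome = a_true + b_true * logit p_model), draws the binary
# outcome, and finally masks values completely at random (MCAR). The raw
# table is emitted with dataset-style integer codes so the mapping layer
# is exercised end to end.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

default_covariate_recipes <- function(spec) {
  lapply(spec$covariates, function(cd) {
    if (cd$kind == "categorical") {
      probs <- if (!is.null(cd$dev_summary$frequencies)) {
        fr <- cd$dev_summary$frequencies
        p <- setNames(rep(0, length(cd$levels)), cd$levels)
        p[names(fr)] <- fr
        p
      } else setNames(rep(1 / length(cd$levels), length(cd$levels)),
                      cd$levels)
      list(type = "categorical", levels = cd$levels, probs = probs)
    } else if (spec$family == "lookup") {
      # draw inside the discretization support so every record matches
      br <- spec$discretization[[cd$name]]$breaks
      list(type = "uniform", min = br[1], max = br[length(br)])
    } else if (!is.null(cd$dev_summary)) {
      list(type = "normal", mean = cd$dev_summary$mean,
           sd = cd$dev_summary$sd)
    } else {
      list(type = "normal", mean = cd$center %||% 0, sd = 1)
    }
  })
}

#' Recipe for a synthetic validation cohort
#'
#' @param spec The true `model_spec` generating the risks.
#' @param n Number of records to draw.
#' @param a_true,b_true Miscalibration applied on the logit scale:
#'   the outcome probability is
#'   `plogis(a_true + b_true * qlogis(p_model))`. `(0, 1)` yields a
#'   perfectly calibrated cohort.
#' @param horizon Prediction horizon used to compute `p_model` (required
#'   for non-logistic families).
#' @param missing_rates Named vector of per-covariate MCAR masking
#'   probabilities in \[0, 1).
#' @param covariate_recipes Optional named list overriding the default
#'   per-covariate sampling distributions
#'   (`list(type = "categorical", levels =, probs =)`,
#'   `list(type = "normal", mean =, sd =)` or
#'   `list(type = "uniform", min =, max =)`). Defaults derive from the
#'   spec's development summaries (lookup models draw continuous
#'   covariates uniformly over their discretization support).
#' @param outcome `list(type = "binary")` (default) or
#'   `list(type = "survival", lambda0 =, censor_window =)`: event times
#'   exponential with rate `lambda0 * exp(logit p_outcome ... )` scaled
#'   per record, uniform censoring on `[0, censor_window]`; records
#'   censored before the horizon are dropped (and counted).
#' @param seed Integer seed; the same recipe and seed reproduce the
#'   cohort byte for byte.
#' @return An object of class `cohort_recipe`.
#' @export
cohort_recipe <- function(spec, n, a_true = 0, b_true = 1, horizon = NULL,
                          missing_rates = NULL, covariate_recipes = NULL,
                          outcome = list(type = "binary"), seed = 1L) {
  if (!inherits(spec, "model_spec"))
    pv_recipe_error("spec must be a model_spec")
  if (!is.numeric(n) || n < 1)
    pv_recipe_error("n must be >= 1")
  if (!is.null(missing_rates)) {
    bad <- setdiff(names(missing_rates), names(spec$covariates))
    if (length(bad))
      pv_recipe_error(sprintf("missing_rates for unknown covariate(s): %s",
                              paste(bad, collapse = ", ")))
    if (any(missing_rates < 0) || any(missing_rates >= 1))
      pv_recipe_error("missing rates must lie in [0, 1)")
  }
  recipes <- default_covariate_recipes(spec)
  if (!is.null(covariate_recipes))
    recipes[names(covariate_recipes)] <- covariate_recipes
  for (nm in names(recipes)) {
    r <- recipes[[nm]]
    if (identical(r$type, "categorical") &&
        abs(sum(r$probs) - 1) > 1e-9)
      pv_recipe_error(sprintf(
        "level probabilities for '%s' must sum to 1", nm))
  }
  if (!outcome$type %in% c("binary", "survival"))
    pv_recipe_error("outcome type must be 'binary' or 'survival'")
  if (outcome$type == "survival" &&
      (is.null(outcome$lambda0) || is.null(outcome$censor_window)))
    pv_recipe_error("survival outcome needs lambda0 and censor_window")
  if (is.null(horizon) && spec$family != "logistic")
    horizon <- if (spec$family == "conditional_logistic")
      max(spec$horizons)  # full cumulative follow-up
    else spec$horizons[1]
  structure(list(spec = spec, n = as.integer(n), a_true = a_true,
                 b_true = b_true, horizon = horizon,
                 missing_rates = missing_rates,
                 covariate_recipes = recipes,
                 outcome = outcome, seed = as.integer(seed)),
            class = "cohort_recipe")
}

# continuous raw codes are formatted once so that the model-scale data
# and the CSV round-trip agree exactly
fmt_num <- function(x) sprintf("%.10g", x)

#' Generate a synthetic validation cohort with known truth
#'
#' Draws the cohort described by a [cohort_recipe()]. Returned are the
#' raw coded table (`raw`, as a cohort CSV would parse), the matching
#' [mapping_config()] (`mapping`), the model-scale data with masked
#' values as `NA` (`data`, including the outcome `y`), and a `truth`
#' record (the miscalibration parameters, realized prevalence, masked
#' counts, and — for survival outcomes — the number of records dropped
#' for pre-horizon censoring).
#'
#' @param recipe A `cohort_recipe`.
#' @return An object of class `synthetic_cohort`.
#' @export
generate_cohort <- function(recipe) {
  if (!inherits(recipe, "cohort_recipe"))
    pv_recipe_error("generate_cohort expects a cohort_recipe")
  spec <- recipe$spec
  n <- recipe$n
  with_seed(recipe$seed, {
    data <- data.frame(row.names = seq_len(n))
    raw <- data.frame(row.names = seq_len(n))
    for (cd in spec$covariates) {
      r <- recipe$covariate_recipes[[cd$name]]
      if (r$type == "categorical") {
        v <- sample(r$levels, n, replace = TRUE, prob = r$probs)
        code <- as.character(match(v, cd$levels))  # dataset-style codes
      } else {
        x <- if (r$type == "uniform") runif(n, r$min, r$max)
        else rnorm(n, r$mean, r$sd)
        code <- fmt_num(x)
        v <- as.numeric(code)
      }
      data[[cd$name]] <- v
      raw[[paste0(cd$name, "_src")]] <- code
    }

    p_model <- predict_risk(spec, data, horizon = recipe$horizon)
    lp_true <- qlogis(pmin(pmax(p_model, 1e-12), 1 - 1e-12))
    p_out <- plogis(recipe$a_true + recipe$b_true * lp_true)

    n_censored_dropped <- 0L
    if (recipe$outcome$type == "binary") {
      y <- rbinom(n, 1L, p_out)
      keep <- rep(TRUE, n)
    } else {
      # exponential event times, rate lambda0 * exp(LP); uniform
      # censoring; pre-horizon censored records are dropped because the
      # validation core requires a fully observed binary status at the
      # horizon
      h <- recipe$horizon %||% spec$horizons[1]
      rate <- recipe$outcome$lambda0 * exp(lp_true)
      tt <- rexp(n, pmax(rate, 1e-12))
      cc <- runif(n, 0, recipe$outcome$censor_window)
      keep <- !(cc < pmin(tt, h))
      n_censored_dropped <- sum(!keep)
      y <- as.integer(tt <= h)
    }
    data$y <- y
    raw$outcome_src <- as.character(y)

    masked <- integer(0)
    if (!is.null(recipe$missing_rates)) {
      for (nm in names(recipe$missing_rates)) {
        rate <- recipe$missing_rates[[nm]]
        if (rate <= 0) next
        m <- runif(n) < rate
        masked[nm] <- sum(m & keep)
        raw[[paste0(nm, "_src")]][m] <- ""
        data[[nm]][m] <- NA
      }
    }
    data <- data[keep, , drop = FALSE]
    raw <- raw[keep, , drop = FALSE]
    rownames(data) <- rownames(raw) <- NULL

    covs <- lapply(spec$covariates, function(cd) {
      if (cd$kind == "categorical")
        list(column = paste0(cd$name, "_src"),
             value_map = setNames(cd$levels,
                                  as.character(seq_along(cd$levels))),
             missing_codes = "")
      else
        list(column = paste0(cd$name, "_src"), scale = 1,
             missing_codes = "")
    })
    mapping <- mapping_config(
      covariates = covs,
      outcome = list(column = "outcome_src", event_code = "1",
                     nonevent_code = "0", missing_codes = ""))

    truth <- list(
      model_id = spec$model_id, seed = recipe$seed,
      a_true = recipe$a_true, b_true = recipe$b_true,
      horizon = recipe$horizon,
      n_requested = n, n = nrow(data),
      prevalence = mean(data$y),
      masked = as.list(masked),
      n_censored_dropped = n_censored_dropped)

    structure(list(raw = raw, mapping = mapping, data = data,
                   truth = truth, recipe = recipe),
              class = "synthetic_cohort")
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes `cohort.csv` (the raw coded table), `mapping.json`, and
#' `truth.json` into a directory. Output is byte-reproducible for a
#' fixed recipe and seed.
#'
#' @param sim A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             mapping = file.path(dir, "mapping.json"),
             truth = file.path(dir, "truth.json"))
  write.csv(sim$raw, paths[["cohort"]], row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  write_mapping(sim$mapping, paths[["mapping"]])
  writeLines(jsonlite::toJSON(sim$truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             paths[["truth"]], useBytes = TRUE)
  invisible(paths)
}

# ---- shipped example specifications ---------------------------------------

example_logistic_spec <- function() {
  model_spec(
    model_id = "example_axillary_logistic", family = "logistic",
    outcome_label = "axillary lymph node metastasis",
    horizons = 1,
    covariates = list(
      covariate_def("node_diameter", "continuous", center = 10,
                    dev_summary = list(mean = 12, sd = 5)),
      covariate_def("cortical_thickness", "continuous", center = 3,
                    dev_summary = list(mean = 3.5, sd = 1.2)),
      covariate_def("hilum", "categorical",
                    levels = c("present", "absent"),
                    reference_level = "present",
                    unknown_weights = c(present = 0.7, absent = 0.3),
                    dev_summary = list(frequencies = c(present = 0.7,
                                                       absent = 0.3))),
      covariate_def("grade", "categorical",
                    levels = c("I", "II", "III"), reference_level = "I",
                    unknown_weights = c(I = 0.3, II = 0.5, III = 0.2),
                    dev_summary = list(frequencies = c(I = 0.3, II = 0.5,
                                                       III = 0.2))),
      covariate_def("tumor_size", "continuous", center = 20,
                    dev_summary = list(mean = 22, sd = 8)),
      covariate_def("er_status", "categorical",
                    levels = c("positive", "negative"),
                    reference_level = "positive",
                    unknown_weights = c(positive = 0.75, negative = 0.25),
                    dev_summary = list(frequencies = c(positive = 0.75,
                                                       negative = 0.25)))),
    intercept = -2.4,
    coefficients = list(
      node_diameter = 0.08, cortical_thickness = 0.35,
      hilum = c(absent = 0.9), grade = c(II = 0.4, III = 0.8),
      tumor_size = 0.03, er_status = c(negative = 0.3)))
}

example_conditional_spec <- function() {
  covs <- list(
    covariate_def("age", "continuous", center = 55,
                  dev_summary = list(mean = 57, sd = 11)),
    covariate_def("tumor_size", "continuous", center = 20,
                  dev_summary = list(mean = 21, sd = 9)),
    covariate_def("nodes", "categorical",
                  levels = c("0", "1-3", "4+"), reference_level = "0",
                  unknown_weights = c(`0` = 0.6, `1-3` = 0.3, `4+` = 0.1),
                  dev_summary = list(frequencies = c(`0` = 0.6,
                                                     `1-3` = 0.3,
                                                     `4+` = 0.1))),
    covariate_def("grade", "categorical",
                  levels = c("I", "II", "III"), reference_level = "I",
                  unknown_weights = c(I = 0.25, II = 0.5, III = 0.25),
                  dev_summary = list(frequencies = c(I = 0.25, II = 0.5,
                                                     III = 0.25))),
    covariate_def("er_status", "categorical",
                  levels = c("positive", "negative"),
                  reference_level = "positive",
                  unknown_weights = c(positive = 0.8, negative = 0.2),
                  dev_summary = list(frequencies = c(positive = 0.8,
                                                     negative = 0.2))))
  # annual risk declines with disease-free years
  intercepts <- c(-5.6, -5.9, -6.1, -6.3, -6.5)
  periods <- lapply(intercepts, function(b0) list(
    intercept = b0,
    coefficients = list(
      age = -0.015, tumor_size = 0.02,
      nodes = c(`1-3` = 0.35, `4+` = 0.7),
      grade = c(II = 0.3, III = 0.6),
      er_status = c(negative = 0.4))))
  model_spec(
    model_id = "example_recurrence_conditional",
    family = "conditional_logistic",
    outcome_label = "locoregional recurrence within 5 years",
    covariates = covs, periods = periods)
}

example_cox_spec <- function() {
  model_spec(
    model_id = "example_survival_cox", family = "cox",
    outcome_label = "death from any cause",
    covariates = list(
      covariate_def("age", "continuous", center = 60,
                    dev_summary = list(mean = 61, sd = 12)),
      covariate_def("tumor_size", "continuous", center = 20,
                    dev_summary = list(mean = 22, sd = 10)),
      covariate_def("nodes", "categorical",
                    levels = c("0", "1-3", "4+"), reference_level = "0",
                    unknown_weights = c(`0` = 0.55, `1-3` = 0.3,
                                        `4+` = 0.15),
                    dev_summary = list(frequencies = c(`0` = 0.55,
                                                       `1-3` = 0.3,
                                                       `4+` = 0.15))),
      covariate_def("grade", "categorical",
                    levels = c("I", "II", "III"), reference_level = "I",
                    unknown_weights = c(I = 0.25, II = 0.5, III = 0.25),
                    dev_summary = list(frequencies = c(I = 0.25, II = 0.5,
                                                       III = 0.25))),
      covariate_def("detection", "categorical",
                    levels = c("screening", "symptomatic"),
                    reference_level = "screening",
                    unknown_weights = c(screening = 0.6,
                                        symptomatic = 0.4),
                    dev_summary = list(frequencies = c(screening = 0.6,
                                                       symptomatic = 0.4)))),
    coefficients = list(
      age = 0.03, tumor_size = 0.015,
      nodes = c(`1-3` = 0.45, `4+` = 0.9),
      grade = c(II = 0.35, III = 0.7),
      detection = c(symptomatic = 0.2)),
    baseline_survival = data.frame(time = c(5, 10),
                                   survival = c(0.945, 0.875)))
}

example_lookup_spec <- function() {
  age_labels <- c("20-49", "50-69", "70-94")
  size_labels <- c("small", "large")
  node_levels <- c("0", "1-3", "4-7")
  keys <- as.vector(outer(
    as.vector(outer(age_labels, size_labels,
                    function(a, s) paste(a, s, sep = "|"))),
    node_levels, function(k, n) paste(k, n, sep = "|")))
  # empirical-style 5-year event probabilities rising with age, size and
  # nodal burden
  grid <- expand.grid(age = seq_along(age_labels),
                      size = seq_along(size_labels),
                      nodes = seq_along(node_levels))
  prob5 <- round(pmin(0.6, 0.04 * grid$age * (1 + 0.6 * (grid$size - 1)) *
                        (1 + 0.9 * (grid$nodes - 1))), 4)
  keys_grid <- paste(age_labels[grid$age], size_labels[grid$size],
                     node_levels[grid$nodes], sep = "|")
  stopifnot(setequal(keys, keys_grid))
  lookup <- rbind(
    data.frame(key = keys_grid, horizon = 5, probability = prob5),
    data.frame(key = keys_grid, horizon = 10,
               probability = round(pmin(0.75, prob5 * 1.7), 4)))
  model_spec(
    model_id = "example_survival_lookup", family = "lookup",
    outcome_label = "death from any cause",
    covariates = list(
      covariate_def("age", "continuous",
                    dev_summary = list(mean = 58, sd = 12)),
      covariate_def("tumor_size", "continuous",
                    dev_summary = list(mean = 21, sd = 10)),
      covariate_def("nodes", "categorical", levels = node_levels,
                    reference_level = "0",
                    dev_summary = list(frequencies = c(`0` = 0.6,
                                                       `1-3` = 0.3,
                                                       `4-7` = 0.1)))),
    discretization = list(
      age = list(breaks = c(20, 50, 70, 95), labels = age_labels),
      tumor_size = list(breaks = c(0, 20, 51), labels = size_labels)),
    lookup_table = lookup)
}

#' Example model specifications, one per supported family
#'
#' Four fully synthetic but realistically shaped specifications: a
#' logistic model for axillary lymph-node metastasis (six covariates,
#' all unknown-capable), a five-period conditional annual-risk model for
#' locoregional recurrence, a Cox model with a 5- and 10-year baseline
#' survival table, and an empirical profile-lookup model. Coefficients
#' are invented; the shapes (covariate mix, horizons, prevalence scale)
#' mirror the models these families are used for in breast-cancer
#' prognosis.
#'
#' @return Named list of four `model_spec` objects (names are the
#'   family names).
#' @export
example_model_specs <- function() {
  list(logistic = example_logistic_spec(),
       conditional_logistic = example_conditional_spec(),
       cox = example_cox_spec(),
       lookup = example_lookup_spec())
}
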