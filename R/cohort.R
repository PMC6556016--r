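# Cohort loading and mapping: translate a validation dataset's columns
# and codes onto the model's covariates and outcome, applying an explicit
# missing-data policy. Missingness is declared (missing_codes), never
# guessed from NA-like tokens.

#' Load a validation cohort from CSV
#'
#' @param path Path to a delimited text file with a header row (UTF-8).
#' @param delimiter Field delimiter, default comma.
#' @return A data frame of character columns, one row per record.
#' @export
load_cohort <- function(path, delimiter = ",") {
  if (!file.exists(path))
    pv_io_error(sprintf("cohort file not found: %s", path))
  raw <- tryCatch(
    read.csv(path, sep = delimiter, colClasses = "character",
             check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e)
      pv_io_error(sprintf("cannot read %s: %s", path, conditionMessage(e))))
  if (ncol(raw) == 0L || nrow(raw) == 0L)
    pv_io_error(sprintf("cohort file %s is empty", path))
  if (anyDuplicated(names(raw)))
    pv_io_error(sprintf("duplicated column name(s) in %s: %s", path,
                        paste(unique(names(raw)[duplicated(names(raw))]),
                              collapse = ", ")))
  raw
}

#' Construct a dataset-to-model mapping configuration
#'
#' Connects each model covariate to a dataset column and translates the
#' dataset's codes to the model's level labels, so cohorts can be
#' validated irrespective of their underlying coding scheme.
#'
#' @param covariates Named list (one entry per model covariate) of
#'   `list(column =, value_map =, scale =, missing_codes =)`:
#'   `value_map` maps dataset codes to model level labels (categorical
#'   covariates only), `scale` is an optional unit conversion factor for
#'   continuous covariates, and `missing_codes` lists dataset codes
#'   treated as missing (the empty string is always treated as missing).
#' @param outcome `list(column =, event_code =, nonevent_code =,
#'   missing_codes =)` identifying the observed binary outcome.
#' @return An object of class `mapping_config`.
#' @export
mapping_config <- function(covariates, outcome) {
  mc <- structure(list(covariates = covariates, outcome = outcome),
                  class = "mapping_config")
  if (is.null(outcome$column) || is.null(outcome$event_code) ||
      is.null(outcome$nonevent_code))
    pv_schema_error("outcome needs column, event_code and nonevent_code",
                    "outcome")
  for (nm in names(covariates)) {
    if (is.null(covariates[[nm]]$column))
      pv_schema_error("covariate mapping needs a source column",
                      sprintf("covariates.%s.column", nm))
  }
  mc
}

#' Load a mapping configuration from JSON
#'
#' @param path Path to a mapping JSON file (see [mapping_config()]).
#' @return A `mapping_config`.
#' @export
load_mapping <- function(path) {
  if (!file.exists(path))
    pv_io_error(sprintf("mapping file not found: %s", path))
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e)
                  pv_parse_error(sprintf("cannot parse %s as JSON: %s",
                                         path, conditionMessage(e))))
  covs <- lapply(x$covariates, function(cm) list(
    column = cm$column,
    value_map = if (!is.null(cm$value_map))
      vapply(cm$value_map, as.character, character(1)),
    scale = if (!is.null(cm$scale)) as.numeric(cm$scale),
    missing_codes = if (!is.null(cm$missing_codes))
      vapply(cm$missing_codes, as.character, character(1)) else character(0)))
  out <- x$outcome
  mapping_config(
    covariates = covs,
    outcome = list(
      column = out$column,
      event_code = as.character(out$event_code),
      nonevent_code = as.character(out$nonevent_code),
      missing_codes = if (!is.null(out$missing_codes))
        vapply(out$missing_codes, as.character, character(1))
      else character(0)))
}

#' Write a mapping configuration to JSON
#'
#' @param mapping A `mapping_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path) {
  covs <- lapply(mapping$covariates, function(cm) {
    out <- list(column = cm$column)
    if (!is.null(cm$value_map)) out$value_map <- as.list(cm$value_map)
    if (!is.null(cm$scale)) out$scale <- cm$scale
    out$missing_codes <- as.list(cm$missing_codes %||% character(0))
    out
  })
  json <- jsonlite::toJSON(
    list(covariates = covs, outcome = list(
      column = mapping$outcome$column,
      event_code = mapping$outcome$event_code,
      nonevent_code = mapping$outcome$nonevent_code,
      missing_codes = as.list(mapping$outcome$missing_codes %||%
                                character(0)))),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

unknown_capable <- function(cd) {
  if (cd$kind == "categorical") !is.null(cd$unknown_weights)
  else !is.null(cd$dev_summary$mean)
}

#' Map a raw cohort onto a model's covariates
#'
#' Translates each record's dataset codes to model levels (categorical)
#' or numbers (continuous), codes the outcome as 1 = event /
#' 0 = non-event, and applies the missing-data policy: with
#' `policy = "to_unknown"` a missing value becomes unknown (`NA`) when
#' the covariate supports unknown scoring (categorical `unknown_weights`
#' or a continuous development mean), otherwise — and always under
#' `policy = "exclude"`, or when the outcome itself is missing — the
#' record is excluded. A code that is neither mapped nor declared missing
#' is a mapping error, not a missing value.
#'
#' @param raw Data frame from [load_cohort()].
#' @param mapping A `mapping_config` covering every model covariate and
#'   the outcome.
#' @param spec The `model_spec` being validated.
#' @param policy `"to_unknown"` (default) or `"exclude"`.
#' @return An object of class `mapped_cohort`: `data` (columns `.row`,
#'   one per covariate, and `y`), `n_input`, `n_excluded`, and
#'   `exclusion_log` (per-variable missing counts and per-record
#'   exclusion reasons).
#' @export
apply_mapping <- function(raw, mapping, spec,
                          policy = c("to_unknown", "exclude")) {
  policy <- match.arg(policy)
  uncovered <- setdiff(names(spec$covariates), names(mapping$covariates))
  if (length(uncovered))
    pv_mapping_error(sprintf("mapping does not cover covariate(s): %s",
                             paste(uncovered, collapse = ", ")))
  n <- nrow(raw)
  get_col <- function(column, what) {
    if (!column %in% names(raw))
      pv_mapping_error(sprintf("%s column '%s' not present in the cohort",
                               what, column))
    as.character(raw[[column]])
  }

  out <- data.frame(.row = seq_len(n))
  missing_by_variable <- integer(0)
  unresolved <- matrix(FALSE, nrow = n,
                       ncol = length(spec$covariates) + 1L,
                       dimnames = list(NULL, c(names(spec$covariates),
                                               ".outcome")))

  for (cd in spec$covariates) {
    cm <- mapping$covariates[[cd$name]]
    codes <- get_col(cm$column, sprintf("covariate '%s'", cd$name))
    miss <- is.na(codes) | codes == "" |
      codes %in% (cm$missing_codes %||% character(0))
    missing_by_variable[cd$name] <- sum(miss)
    if (cd$kind == "categorical") {
      vm <- cm$value_map
      if (is.null(vm))
        pv_mapping_error(sprintf(
          "categorical covariate '%s' needs a value_map", cd$name))
      bad_target <- setdiff(unname(vm), cd$levels)
      if (length(bad_target))
        pv_mapping_error(sprintf(
          "value_map for '%s' targets undeclared level(s): %s",
          cd$name, paste(bad_target, collapse = ", ")))
      unseen <- !miss & !(codes %in% names(vm))
      if (any(unseen)) {
        i <- which(unseen)[1]
        pv_mapping_error(sprintf(
          "column '%s': code '%s' is neither mapped nor declared missing (first at row %d)",
          cm$column, codes[i], i))
      }
      vals <- rep(NA_character_, n)
      vals[!miss] <- unname(vm[codes[!miss]])
    } else {
      suppressWarnings(num <- as.numeric(codes))
      bad <- !miss & is.na(num)
      if (any(bad)) {
        i <- which(bad)[1]
        pv_mapping_error(sprintf(
          "column '%s': code '%s' is not numeric and not declared missing (first at row %d)",
          cm$column, codes[i], i))
      }
      vals <- num * (cm$scale %||% 1)
      vals[miss] <- NA_real_
    }
    # a missing value survives only under to_unknown on an
    # unknown-capable covariate; otherwise the record must go
    resolvable <- policy == "to_unknown" && unknown_capable(cd)
    if (!resolvable) unresolved[miss, cd$name] <- TRUE
    out[[cd$name]] <- vals
  }

  oc <- mapping$outcome
  ocodes <- get_col(oc$column, "outcome")
  omiss <- is.na(ocodes) | ocodes == "" |
    ocodes %in% (oc$missing_codes %||% character(0))
  known <- !omiss & (ocodes %in% c(oc$event_code, oc$nonevent_code))
  if (any(!omiss & !known)) {
    i <- which(!omiss & !known)[1]
    pv_mapping_error(sprintf(
      "outcome column '%s': unrecognized code '%s' (first at row %d)",
      oc$column, ocodes[i], i))
  }
  missing_by_variable[".outcome"] <- sum(omiss)
  unresolved[omiss, ".outcome"] <- TRUE
  y <- rep(NA_integer_, n)
  y[!omiss] <- as.integer(ocodes[!omiss] == oc$event_code)
  out$y <- y

  drop <- rowSums(unresolved) > 0
  reasons <- apply(unresolved[drop, , drop = FALSE], 1L, function(r)
    paste(colnames(unresolved)[r], collapse = ","))
  excluded <- data.frame(.row = which(drop),
                         reason = if (length(reasons)) reasons
                         else character(0))
  structure(list(
    data = out[!drop, , drop = FALSE],
    n_input = n,
    n_excluded = sum(drop),
    policy = policy,
    exclusion_log = list(missing_by_variable = missing_by_variable,
                         excluded = excluded)
  ), class = "mapped_cohort")
}

#' @export
print.mapped_cohort <- function(x, ...) {
  cat(sprintf("<mapped_cohort> %d records retained of %d (%d excluded, policy '%s')\n",
              nrow(x$data), x$n_input, x$n_excluded, x$policy))
  mv <- x$exclusion_log$missing_by_variable
  mv <- mv[mv > 0]
  if (length(mv))
    cat("  missing values:",
        paste(sprintf("%s=%d", names(mv), mv), collapse = ", "), "\n")
  invisible(x)
}

#' Compare validation-cohort baseline characteristics with the
#' development cohort
#'
#' For every covariate whose spec carries a development summary
#' (`dev_summary`), compares the validation cohort's distribution against
#' it: continuous covariates by the standardized mean difference with
#' pooled SD, categorical covariates by per-level standardized
#' differences of proportions (overall statistic: the largest absolute
#' per-level difference). Absolute standardized differences above 0.1 are
#' flagged as potentially influencing validation outcomes. Covariates
#' without a development summary are listed as not comparable.
#'
#' @param spec A `model_spec`.
#' @param cohort A `mapped_cohort`.
#' @return An object of class `baseline_comparison`: `table` (covariate,
#'   kind, std_diff, flag), `details` (per-covariate level frequencies or
#'   moments), `not_comparable` (covariate names lacking a dev summary).
#' @export
compare_baseline <- function(spec, cohort) {
  dat <- cohort$data
  rows <- list()
  details <- list()
  not_comparable <- character(0)
  for (cd in spec$covariates) {
    v <- dat[[cd$name]]
    v <- v[!is.na(v)]
    if (is.null(cd$dev_summary)) {
      not_comparable <- c(not_comparable, cd$name)
      next
    }
    if (cd$kind == "categorical") {
      dev <- cd$dev_summary$frequencies
      dev <- setNames(as.numeric(dev[cd$levels]), cd$levels)
      dev[is.na(dev)] <- 0
      val <- if (length(v))
        as.numeric(table(factor(v, levels = cd$levels))) / length(v)
      else rep(NA_real_, length(cd$levels))
      per_level <- (val - dev) /
        sqrt((val * (1 - val) + dev * (1 - dev)) / 2)
      per_level[which(val == dev)] <- 0  # includes both-zero levels
      smd <- if (all(is.na(per_level))) NA_real_
      else max(abs(per_level), na.rm = TRUE)
      details[[cd$name]] <- data.frame(
        level = cd$levels, dev_freq = dev, val_freq = val,
        std_diff = per_level, row.names = NULL)
    } else {
      m1 <- if (length(v)) mean(v) else NA_real_
      s1 <- if (length(v) > 1) sd(v) else NA_real_
      m0 <- cd$dev_summary$mean
      s0 <- cd$dev_summary$sd
      pooled <- sqrt((s1^2 + s0^2) / 2)
      smd <- (m1 - m0) / pooled
      details[[cd$name]] <- data.frame(
        dev_mean = m0, dev_sd = s0, val_mean = m1, val_sd = s1)
    }
    rows[[cd$name]] <- data.frame(
      covariate = cd$name, kind = cd$kind, std_diff = smd,
      flag = !is.na(smd) && abs(smd) > 0.1)
  }
  if (!length(rows))
    warning("no covariate carries a development summary; ",
            "baseline comparison is empty")
  structure(list(
    table = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else data.frame(covariate = character(0), kind = character(0),
                    std_diff = numeric(0), flag = logical(0)),
    details = details,
    not_comparable = not_comparable
  ), class = "baseline_comparison")
}

#' @export
print.baseline_comparison <- function(x, ...) {
  cat("<baseline_comparison>\n")
  if (nrow(x$table)) print(x$table) else cat("  (empty)\n")
  if (length(x$not_comparable))
    cat("  not comparable (no development summary):",
        paste(x$not_comparable, collapse = ", "), "\n")
  invisible(x)
}
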