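# Validation reports: a serializable record of one validation run
# (cohort provenance, calibration, discrimination, baseline comparison)
# plus its graphical outputs — the decile calibration plot against the
# perfect prediction line y = x and the ROC curve.

#' Assemble a validation report
#'
#' Bundles the numeric results of [validate_model()] with cohort
#' provenance and configuration into a single serializable object. Every
#' number in the report equals the corresponding result-object field;
#' rounding to 2 decimals happens only in the plain-text display form.
#'
#' @param result A `validation_result`.
#' @param cohort The `mapped_cohort` that was validated.
#' @param baseline Optional `baseline_comparison`.
#' @param cohort_file Source path of the cohort (provenance only).
#' @param config Named list echoing the run configuration.
#' @return An object of class `validation_report`.
#' @export
validation_report <- function(result, cohort, baseline = NULL,
                              cohort_file = NULL, config = list()) {
  structure(list(
    report_version = "1",
    tool_version = as.character(packageVersion("predvalid")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    model_id = result$model_id,
    horizon = result$horizon,
    cohort = list(file = cohort_file,
                  n_input = cohort$n_input,
                  n_retained = nrow(cohort$data),
                  n_excluded = cohort$n_excluded,
                  policy = cohort$policy,
                  missing_by_variable =
                    as.list(cohort$exclusion_log$missing_by_variable)),
    calibration = list(
      intercept = result$calibration$intercept,
      slope = result$calibration$slope,
      intercept_unrestricted = result$calibration$intercept_unrestricted,
      n_bins = result$calibration$n_bins,
      eps = result$calibration$eps,
      bins = result$calibration$bins),
    discrimination = list(auc = result$discrimination$auc,
                          n_events = result$discrimination$n_events,
                          n_nonevents = result$discrimination$n_nonevents,
                          roc = result$discrimination$roc),
    baseline = if (!is.null(baseline)) list(
      table = baseline$table,
      not_comparable = baseline$not_comparable),
    config = config
  ), class = "validation_report")
}

#' Calibration plot (observed vs predicted, grouped)
#'
#' @param bins Bin table from [calibration_bins()].
#' @return A ggplot object: per-group observed proportions with 95%
#'   Wilson intervals against mean predicted risk, with the perfect
#'   prediction line `y = x` for reference.
#' @export
plot_calibration <- function(bins) {
  lim <- c(0, max(bins$mean_predicted, bins$ci_high, 0.01) * 1.05)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mean_predicted,
                                     y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0, colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::coord_cartesian(xlim = lim, ylim = lim) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed proportion (95% CI)",
                  title = "Calibration") +
    ggplot2::theme_minimal()
}

#' ROC plot
#'
#' @param roc ROC table from [roc_and_auc()] (`fpr`, `sensitivity`).
#' @param auc AUC annotated in the subtitle.
#' @return A ggplot object.
#' @export
plot_roc <- function(roc, auc = NULL) {
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = "ROC curve",
                  subtitle = if (!is.null(auc))
                    sprintf("AUC = %.2f", auc)) +
    ggplot2::theme_minimal()
}

report_to_list <- function(report) {
  x <- unclass(report)
  x$calibration$bins <- lapply(seq_len(nrow(x$calibration$bins)),
    function(i) as.list(x$calibration$bins[i, ]))
  x$discrimination$roc <- lapply(seq_len(nrow(x$discrimination$roc)),
    function(i) as.list(x$discrimination$roc[i, ]))
  if (!is.null(x$baseline))
    x$baseline$table <- lapply(seq_len(nrow(x$baseline$table)),
      function(i) as.list(x$baseline$table[i, ]))
  x
}

#' Read a validation report back from JSON
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return A `validation_report` equal to the one written.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows_to_df <- function(rows) {
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  x$calibration$bins <- rows_to_df(x$calibration$bins)
  x$discrimination$roc <- rows_to_df(x$discrimination$roc)
  x$discrimination$roc$threshold <-
    as.numeric(x$discrimination$roc$threshold)  # "Inf" comes back as text
  if (!is.null(x$baseline)) {
    x$baseline$table <- rows_to_df(x$baseline$table)
    x$baseline$not_comparable <-
      as.character(unlist(x$baseline$not_comparable))
  }
  if (!is.null(x$horizon)) x$horizon <- as.numeric(x$horizon)
  x$calibration$n_bins <- as.integer(x$calibration$n_bins)
  x$cohort$missing_by_variable <-
    lapply(x$cohort$missing_by_variable, as.integer)
  x$config <- x$config %||% list()
  structure(x, class = "validation_report")
}

#' Write a validation report and its figures
#'
#' Writes `report.json` (full precision, schema-versioned),
#' `calibration.svg` / `calibration.png` (grouped observed-vs-predicted
#' with 95% CI bars and the `y = x` reference line), `roc.svg` /
#' `roc.png`, and `summary.txt` containing a one-line summary with
#' intercept, slope and AUC rounded to 2 decimals.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) pv_io_error(sprintf("cannot create output directory %s", dir))
  }
  paths <- c(report = file.path(dir, "report.json"),
             calibration_svg = file.path(dir, "calibration.svg"),
             calibration_png = file.path(dir, "calibration.png"),
             roc_svg = file.path(dir, "roc.svg"),
             roc_png = file.path(dir, "roc.png"),
             summary = file.path(dir, "summary.txt"))
  json <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
  writeLines(json, paths[["report"]], useBytes = TRUE)

  cal <- plot_calibration(report$calibration$bins)
  roc <- plot_roc(report$discrimination$roc, report$discrimination$auc)
  save_plot <- function(p, svg_path, png_path) {
    grDevices::svg(svg_path, width = 5, height = 5)
    print(p)
    grDevices::dev.off()
    grDevices::png(png_path, width = 1000, height = 1000, res = 200)
    print(p)
    grDevices::dev.off()
  }
  save_plot(cal, paths[["calibration_svg"]], paths[["calibration_png"]])
  save_plot(roc, paths[["roc_svg"]], paths[["roc_png"]])

  summary_lines <- c(
    sprintf("model: %s", report$model_id),
    sprintf("cohort: n_input=%d, retained=%d, excluded=%d (policy %s)",
            report$cohort$n_input, report$cohort$n_retained,
            report$cohort$n_excluded, report$cohort$policy),
    if (!is.null(report$horizon))
      sprintf("horizon: %g years", report$horizon),
    sprintf("intercept, slope, AUC: %.2f, %.2f, %.2f",
            report$calibration$intercept, report$calibration$slope,
            report$discrimination$auc))
  writeLines(summary_lines, paths[["summary"]])
  invisible(paths)
}
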