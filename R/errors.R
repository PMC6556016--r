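# Classed conditions so callers (and the CLI) can distinguish failure modes.

pv_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "pv_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

pv_parse_error      <- function(msg, ...) pv_abort(msg, "pv_parse_error", ...)
pv_schema_error     <- function(msg, field = NULL, ...) {
  if (!is.null(field)) msg <- sprintf("%s [field: %s]", msg, field)
  pv_abort(msg, "pv_schema_error", field = field, ...)
}
pv_mapping_error    <- function(msg, ...) pv_abort(msg, "pv_mapping_error", ...)
pv_unknown_error    <- function(msg, ...) pv_abort(msg, "pv_unknown_error", ...)
pv_horizon_error    <- function(msg, ...) pv_abort(msg, "pv_horizon_error", ...)
pv_profile_error    <- function(msg, ...) pv_abort(msg, "pv_profile_error", ...)
pv_degenerate_error <- function(msg, ...) pv_abort(msg, "pv_degenerate_error", ...)
pv_bin_error        <- function(msg, ...) pv_abort(msg, "pv_bin_error", ...)
pv_fit_error        <- function(msg, ...) pv_abort(msg, "pv_fit_error", ...)
pv_recipe_error     <- function(msg, ...) pv_abort(msg, "pv_recipe_error", ...)
pv_io_error         <- function(msg, ...) pv_abort(msg, "pv_io_error", ...)
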