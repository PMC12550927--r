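# Classed conditions so callers can distinguish failure modes programmatically.

ddStop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "ddScreenError")))
}

#' @title Error classes used by ddScreen
#' @description All errors raised by the package inherit from
#'   `ddScreenError` plus a specific class: `ddSaturationError` (all or too
#'   many droplets positive), `ddNoReferenceError` (RPP30 concentration zero),
#'   `ddInsufficientDataError`, `ddSchemaError` (malformed input table),
#'   `ddConfigError` (invalid configuration), `ddQCError` (QC-excluded well),
#'   `ddPreconditionError`.
#' @name ddScreen-conditions
#' @keywords internal
NULL
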