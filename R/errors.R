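# Classed conditions used across the package. Every domain error is an
# rlang abort with class "cellmapr_<snake>" so callers can catch selectively.

cm_stop <- function(class, message, ...) {
  rlang::abort(message, class = paste0("cellmapr_", class), ...)
}

#' @importFrom rlang abort warn inform
NULL

cm_warn <- function(message) rlang::warn(message, class = "cellmapr_warning")

# Internal logging: counted warnings (skipped cells, empty bins) surface as
# messages and are returned as attributes where the spec asks for counts.
cm_log <- function(...) {
  if (isTRUE(getOption("cellmapr.quiet", TRUE))) return(invisible(NULL))
  message(sprintf(...))
}
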