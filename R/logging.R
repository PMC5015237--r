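#' Package logging
#'
#' Every threshold, geometry and tie-break decision taken by the pipeline is
#' reported through a small levelled logger.  The level is controlled by
#' `options(slndetect.log_level = )` with levels `"DEBUG" < "INFO" <
#' "WARN" < "NONE"`; the default is `"WARN"` so ordinary use is quiet while
#' warnings still surface.
#'
#' @param level One of `"DEBUG"`, `"INFO"`, `"WARN"`.
#' @param ... Message parts, pasted together with [sprintf()]-free
#'   concatenation.
#' @return Invisibly, the message string (emitted or not).
#' @keywords internal
sln_log <- function(level = "INFO", ...) {
  ranks <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, NONE = 4L)
  cur <- getOption("slndetect.log_level", "WARN")
  msg <- paste0(...)
  if (ranks[[level]] >= ranks[[cur]]) {
    message(sprintf("[slndetect %s] %s", level, msg))
  }
  invisible(msg)
}
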