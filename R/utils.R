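# Internal helpers: classed conditions and structured logging.

stop_stkrige <- function(class, message, ...) {
  stop(structure(
    class = c(class, "stkrige_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

warn_stkrige <- function(class, message, ...) {
  warning(structure(
    class = c(class, "stkrige_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Structured log events: emitted as messages with class "stkrige_log" so
# callers (and tests) can capture stage/event/counts programmatically.
log_event <- function(stage, event, ...) {
  fields <- list(...)
  txt <- paste0(
    "[", stage, "] ", event,
    if (length(fields)) {
      paste0(" ", paste(names(fields), unlist(fields), sep = "=", collapse = " "))
    } else "",
    "\n"
  )
  message(structure(
    class = c("stkrige_log", "message", "condition"),
    list(message = txt, stage = stage, event = event, fields = fields)
  ))
  invisible(NULL)
}

assert_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop_stkrige("stkrige_invalid_input", sprintf("'%s' must be finite", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seeds drawn for sub-tasks must stay below .Machine$integer.max.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(k) %% 1000003L
}
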