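#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and tests) can distinguish validation failures.
# Every error gets class c("mcda4hta_<code>", "mcda4hta_error", "error", "condition").
mcda_stop <- function(code, fmt, ..., call = sys.call(-1)) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg,
    class = c(paste0("mcda4hta_", code), "mcda4hta_error")
  ))
}

mcda_warn <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  warning(warningCondition(msg,
    class = c(paste0("mcda4hta_", code), "mcda4hta_warning")
  ))
}

# Stage-tagged log line used by the pipeline; collected into the decision
# report so warnings (CR > 0.1, dropped columns) are part of the record.
mcda_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
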