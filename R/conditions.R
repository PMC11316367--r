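# Structured error conditions: every user-facing failure carries a condition
# class so callers (and the CLI) can branch on the failure kind rather than on
# message text.

abort_gpc <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "gpcoverage_error"),
                      call = call))
}

warn_gpc <- function(message, class) {
  warning(warningCondition(message, class = c(class, "gpcoverage_warning")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
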