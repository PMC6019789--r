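# Condition constructors. Three families are distinguished so callers (and
# the engine's retry policy) can react differently:
#   bamsieve_validation_error - bad arguments / malformed specs; never retried
#   bamsieve_io_error         - unreachable or unreadable source/sink; retryable
#   bamsieve_parse_error      - malformed record content; not retryable

stop_validation <- function(...) {
  stop(structure(
    class = c("bamsieve_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_io <- function(..., retryable = TRUE) {
  stop(structure(
    class = c("bamsieve_io_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1), retryable = retryable)
  ))
}

stop_parse <- function(...) {
  stop(structure(
    class = c("bamsieve_parse_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_retryable <- function(cond) {
  inherits(cond, "bamsieve_io_error") && isTRUE(cond$retryable)
}
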