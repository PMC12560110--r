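# Internal condition constructors. Data errors (malformed or inconsistent
# input) and usage errors (bad arguments/flags) carry distinct classes so the
# command-line wrapper can map them to exit codes 1 and 2.

data_error <- function(msg, ...) {
  stop(structure(
    class = c("symcurate_data_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

usage_error <- function(msg, ...) {
  stop(structure(
    class = c("symcurate_usage_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
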