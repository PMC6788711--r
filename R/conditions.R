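# Condition classes used across the package so callers (and the command-line
# front end) can map failures to distinct exit codes.

abort_validation <- function(message, ...) {
  rlang::abort(message, class = "rmn_validation_error", ...)
}

abort_io <- function(message, ...) {
  rlang::abort(message, class = "rmn_io_error", ...)
}

abort_infeasible <- function(message, ...) {
  rlang::abort(message, class = "rmn_infeasible_error", ...)
}

is_binary01 <- function(x) {
  !is.na(x) & (x == 0 | x == 1)
}

check_count <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    abort_validation(sprintf("`%s` must contain nonnegative integers.", name))
  }
  invisible(x)
}
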