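# Internal helpers: argument checking and condition classes.
#
# Three error classes are used throughout so callers (and the command-line
# driver) can map failures to exit codes:
#   attencor_config_error  - invalid parameters / schema violations
#   attencor_numeric_error - numerical failure (solver breakdown, ...)
#   attencor_io_error      - file system problems

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("attencor_config_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("attencor_numeric_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("attencor_io_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_config("'", name, "' must be a single non-missing number")
  if (finite && !is.finite(x))
    stop_config("'", name, "' must be finite")
  if (x < lower || x > upper)
    stop_config("'", name, "' must be in [", lower, ", ", upper, "], got ", x)
  as.numeric(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x))
    stop_config("'", name, "' must be a single integer")
  if (x < lower)
    stop_config("'", name, "' must be >= ", lower)
  as.integer(x)
}

check_seed <- function(seed) {
  check_count(seed, "seed", lower = -.Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
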