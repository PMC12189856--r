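#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and tests) can distinguish failure modes.
stop_validation <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("ctesm_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_format <- function(msg) {
  stop(structure(
    class = c("ctesm_format_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_config <- function(msg) {
  stop(structure(
    class = c("ctesm_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_positive_scalar <- function(x, name, integer = FALSE, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (allow_zero) x >= 0 else x > 0) && (!integer || x == round(x))
  if (!ok) {
    stop_validation(sprintf(
      "field '%s' must be a %s%s scalar, got: %s",
      name,
      if (allow_zero) "non-negative" else "positive",
      if (integer) " integer" else "",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# global RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream seed from a base seed and a counter, staying inside the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 1000000007 + counter * 1009) %% 2147483647)
}

# Periodic Hann taper (matches the scipy/Matlab 'periodic' convention used
# for spectral estimation).
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
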