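# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_invalid("`", name, "` must be a single positive number")
  }
  invisible(x)
}

check_nonnegative_force <- function(force) {
  if (!is.numeric(force) || any(is.na(force)) || any(force < 0)) {
    stop_invalid("`force` must be non-negative (pN)")
  }
  invisible(force)
}
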