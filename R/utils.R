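# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

stop_bad_arg <- function(name, msg) {
  stop(sprintf("invalid `%s`: %s", name, msg), call. = FALSE)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad_arg(name, "must be a single finite number")
  }
  if (x < min || x > max) {
    stop_bad_arg(name, sprintf("must be in [%s, %s], got %s", min, max, x))
  }
  if (integerish && x != round(x)) {
    stop_bad_arg(name, sprintf("must be a whole number, got %s", x))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
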