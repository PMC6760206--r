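# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed bisre error
#'
#' All user-facing errors carry a subclass so callers (and the pipeline
#' driver) can distinguish configuration, argument, schema, capability,
#' fitting and validation failures.
#'
#' @param message error message.
#' @param class error subclass, e.g. "bisre_argument_error".
#' @param ... additional condition fields.
#' @noRd
abort_bisre <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "bisre_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library code never
#' perturbs the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a master seed
#'
#' Keeps results below 2^31 - 1 so the value is a valid R integer seed.
#' @noRd
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729) %%
               2147483646) + 1L
}

# Ensure a scalar is a finite number; used in config validation.
check_number <- function(x, name, min = -Inf, max = Inf,
                         class = "bisre_config_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort_bisre(
      sprintf("field '%s' must be a finite number in [%s, %s]",
              name, format(min), format(max)),
      class
    )
  }
  invisible(x)
}
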