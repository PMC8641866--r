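# Classed error helpers so callers can distinguish bad parameters, bad inputs
# and degenerate (but well-formed) inputs.

rf_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "rfarn_error", "error", "condition"),
    list(message = msg, call = sys.call(-2))
  ))
}

abort_param <- function(msg) rf_abort(msg, "rfarn_invalid_parameter")
abort_input <- function(msg) rf_abort(msg, "rfarn_invalid_input")
abort_degenerate <- function(msg) rf_abort(msg, "rfarn_degenerate_input")
abort_io <- function(msg) rf_abort(msg, "rfarn_io_error")

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
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

# derive a per-stage child seed from a root seed, kept inside 32-bit range
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L %% 2147483647L + as.integer(k)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)
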