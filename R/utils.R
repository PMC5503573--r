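# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves going up (away from
#' zero), the convention used when formatting percentages for display.  Base
#' [round()] rounds half to even, which disagrees with the reported-percentage
#' convention on values such as 84.755.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(84.755, 2) # 84.76
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# stop() with a consistent condition class so tests can assert error types
ms_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "metabscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Run code with a private RNG stream: seeds the global RNG, restores the
# previous state on exit so callers' RNG streams are untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# sample that never interprets a length-1 x as 1:x
sample_vec <- function(x, size = length(x)) x[sample.int(length(x), size)]

stopifnot_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    ms_stop(sprintf("'%s' must be a single integer >= %d", name, min),
            "config_error")
  }
}
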