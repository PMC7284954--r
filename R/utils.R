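#' Round half-up to a fixed number of decimals
#'
#' Base R's \code{round()} uses banker's rounding (round-half-even), but the
#' conventions used throughout this package round halves away from zero:
#' 0.25 rounds to 0.3 at one decimal, 12.5 to 13 at zero decimals.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.25, 2.05, 12.5), c(1, 1, 0))
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # small epsilon guards against 2.05 being stored as 2.04999...
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Express a count fraction as a whole percent
#'
#' @param numerator,denominator non-negative counts.
#' @return integer percent, rounded half-up.
#' @examples
#' percent_of(20, 162)   # 12
#' percent_of(2829, 10514) # 27
#' @export
percent_of <- function(numerator, denominator) {
  stopifnot(denominator > 0, numerator >= 0)
  round_half_up(100 * numerator / denominator, 0)
}

# internal: run expr with a temporary RNG seed without clobbering global state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# internal: stop with a stage-labelled message
abort_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
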