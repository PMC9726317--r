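#' Round half-down
#'
#' Rounds to the nearest integer with exact halves rounded towards zero
#' (4.5 -> 4, 37.5 -> 37). This is the rounding rule used throughout the
#' decision-model reports, chosen because it reproduces the published
#' half-valued cells.
#'
#' A small absolute tolerance (1e-9) absorbs floating-point noise around
#' exact halves (e.g. `30 * (1 - 0.85)` evaluates just above 4.5).
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @return Integer-valued numeric vector.
#' @export
#' @examples
#' round_half_down(c(4.5, 37.5, 7.965, 0.9))
round_half_down <- function(x) {
  ceiling(x - 0.5 - 1e-9)
}

# internal: stop unless all values are probabilities in [0, 1]
check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

# internal: stop unless all values are 0/1
check_binary <- function(x, what) {
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop(sprintf("'%s' must be a binary 0/1 indicator", what), call. = FALSE)
  }
  invisible(x)
}
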