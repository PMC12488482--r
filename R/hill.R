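#' Hill activation and inhibition fractions
#'
#' `hill_up()` returns the activating Hill fraction x^n / (k^n + x^n);
#' `hill_down()` returns the inhibitory fraction k^n / (k^n + x^n). The two
#' are exact complements: `hill_up(x, k, n) + hill_down(x, k, n) == 1`.
#' These are the only nonlinearities in the feedforward-loop model, so every
#' drive term is a fraction in \[0, 1\] and the dynamics map the unit
#' hypercube into itself.
#'
#' At `x = 0` the functions return exactly 0 (up) and 1 (down), avoiding
#' `0^n` edge cases for non-integer Hill coefficients.
#'
#' @param x Non-negative input level (vectorised).
#' @param k Half-maximal constant, strictly positive.
#' @param n Hill coefficient, at least 1.
#' @return Numeric vector of fractions in \[0, 1\], same length as `x`.
#' @examples
#' hill_up(3, 0.2, 1)    # 0.9375
#' hill_down(0.4, 0.4, 3) # 0.5
#' @export
hill_up <- function(x, k, n) {
  check_hill_args(x, k, n)
  out <- numeric(length(x))
  nz <- x > 0
  xn <- x[nz]^n
  out[nz] <- xn / (k^n + xn)
  out
}

#' @rdname hill_up
#' @export
hill_down <- function(x, k, n) {
  1 - hill_up(x, k, n)
}

check_hill_args <- function(x, k, n) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("`x` must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("`k` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be a single number >= 1", call. = FALSE)
  }
  invisible(TRUE)
}
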