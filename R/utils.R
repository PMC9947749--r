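#' Round half away from zero at a fixed number of decimals
#'
#' Printed tables in survey and topography reports conventionally use
#' "half-up" rounding (0.005 -> 0.01), whereas base [round()] rounds half to
#' even. A small epsilon guards against binary representation error for
#' values an unlucky ulp below a half boundary.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2) # 0.13, 0.14
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Coefficient of variation, in percent
#'
#' 100 * sample SD / mean. Undefined (NA) when fewer than two observations
#' or when the mean is not strictly positive; never silently zero.
#'
#' @param x numeric vector (NAs dropped).
#' @return scalar CV in percent, or NA when undefined.
#' @export
cv_pct <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (!(m > 0)) return(NA_real_)
  100 * stats::sd(x) / m
}

# internal: stop with a classed condition so callers/tests can be specific
abort_pufftopo <- function(msg, class) {
  rlang::abort(msg, class = c(class, "pufftopo_error"))
}
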