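# Internal numeric helpers shared across modules.

# Trapezoidal quadrature weights for an arbitrary strictly increasing grid.
# sum(trapz_weights(x) * y) == trapezoidal integral of y over x.
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  dx <- diff(x)
  w <- numeric(n)
  w[1L] <- dx[1L] / 2
  w[n] <- dx[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dx[-1L] + dx[-(n - 1L)]) / 2
  w
}

trapz <- function(x, y) sum(trapz_weights(x) * y)

# Round to `digits` significant figures, half away from zero (report style:
# 3.8, 5.6, 13, 32). Full-precision values are always kept alongside.
round_signif <- function(x, digits = 2L) {
  out <- x
  nz <- is.finite(x) & x != 0
  if (any(nz)) {
    m <- floor(log10(abs(x[nz])))
    f <- 10^(digits - 1L - m)
    out[nz] <- sign(x[nz]) * floor(abs(x[nz]) * f + 0.5) / f
  }
  out
}

# Lag-1 autocorrelation of a vector; smooth signal-like vectors score near 1,
# white noise near 0. Returns 0 for degenerate (constant) input.
lag1_autocorr <- function(x) {
  x <- x - mean(x)
  denom <- sum(x^2)
  if (denom == 0) return(0)
  sum(x[-length(x)] * x[-1L]) / denom
}

# Log-spaced pump-probe delay grids. Half-decade spacing from 10 us to
# 316 ms gives exactly 10 delays; quarter-decade from 31.6 us to 100 ms
# gives exactly 15.
#' Standard log-spaced pump-probe delay grids
#'
#' Generates the two delay series used throughout the package: half-decade
#' spacing (10 us to 316 ms, 10 delays) and quarter-decade spacing
#' (31.6 us to 100 ms, 15 delays).
#'
#' @param spacing `"half-decade"` or `"quarter-decade"`.
#' @return Numeric vector of delays in seconds, strictly increasing.
#' @examples
#' length(delay_grid("half-decade"))     # 10
#' length(delay_grid("quarter-decade"))  # 15
#' @export
delay_grid <- function(spacing = c("half-decade", "quarter-decade")) {
  spacing <- match.arg(spacing)
  if (spacing == "half-decade") 10^seq(-5, -0.5, by = 0.5) else 10^seq(-4.5, -1, by = 0.25)
}

stop_sxl <- function(message, class) {
  abort(message, class = c(class, "sxl_error"))
}

check_number <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_sxl(sprintf("`%s` must be a single finite number.", name), "sxl_invalid_parameter")
  }
  if (positive && x <= 0) {
    stop_sxl(sprintf("`%s` must be > 0 (got %g).", name, x), "sxl_invalid_parameter")
  }
  if (non_negative && x < 0) {
    stop_sxl(sprintf("`%s` must be >= 0 (got %g).", name, x), "sxl_invalid_parameter")
  }
  invisible(x)
}
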