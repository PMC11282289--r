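#' One-dimensional scattering curve
#'
#' A scattering curve is a tibble with columns `q` (inverse Angstrom,
#' strictly increasing), `intensity` and `sigma` (same arbitrary units),
#' carrying exposure metadata (chamber row/col, laser state, pump-probe
#' delay, exposure index) as attributes. All reduction operations take and
#' return this shape, so they chain with the pipe.
#'
#' @param q Strictly increasing momentum-transfer grid, inverse Angstrom.
#' @param intensity Intensity values, arbitrary units.
#' @param sigma Per-point 1-sigma uncertainties (>= 0); scalar is recycled.
#' @param chamber Integer vector `c(row, col)` or `NULL`.
#' @param laser_state `"on"`, `"off"` or `NA`.
#' @param delay Pump-probe delay in seconds, or `NA`.
#' @param exposure_index Position in the exposure sequence, or `NA`.
#' @return A tibble of class `sxl_curve`.
#' @export
scattering_curve <- function(q, intensity, sigma = 0,
                             chamber = NULL, laser_state = NA_character_,
                             delay = NA_real_, exposure_index = NA_integer_) {
  if (length(q) != length(intensity)) {
    stop_sxl("q and intensity must have equal length.", "sxl_invalid_parameter")
  }
  if (is.unsorted(q, strictly = TRUE)) {
    stop_sxl("q must be strictly increasing.", "sxl_grid_error")
  }
  sigma <- rep_len(sigma, length(q))
  if (any(sigma < 0)) stop_sxl("sigma must be >= 0.", "sxl_invalid_parameter")
  out <- tibble(q = as.numeric(q), intensity = as.numeric(intensity), sigma = as.numeric(sigma))
  class(out) <- c("sxl_curve", class(out))
  attr(out, "meta") <- list(
    chamber = chamber, laser_state = laser_state,
    delay = delay, exposure_index = exposure_index,
    replaced_points = integer()
  )
  out
}

curve_meta <- function(curve) attr(curve, "meta") %||% list()

set_curve_meta <- function(curve, meta) {
  attr(curve, "meta") <- meta
  curve
}

#' Hampel despiking of a scattering curve
#'
#' Detector spikes are replaced by the local rolling median: a point is an
#' outlier when it deviates from the median of its window by more than
#' `n_sigma * 1.4826 * MAD` of that window. Edge windows are truncated.
#' Indices of replaced points are recorded in the curve metadata
#' (`attr(., "meta")$replaced_points`).
#'
#' @param curve An [scattering_curve()].
#' @param window Window half-width in points (full window `2*window + 1`).
#' @param n_sigma Rejection threshold in robust-sigma units.
#' @return The despiked curve.
#' @export
hampel_despike <- function(curve, window = 5L, n_sigma = 3) {
  check_number(window, "window", positive = TRUE)
  check_number(n_sigma, "n_sigma", positive = TRUE)
  window <- as.integer(window)
  n <- nrow(curve)
  if (2L * window + 1L > n) {
    stop_sxl(sprintf("window (half-width %d) exceeds curve length %d.", window, n),
             "sxl_invalid_parameter")
  }
  y <- curve$intensity
  med <- numeric(n)
  dev_ok <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window)
    hi <- min(n, i + window)
    w <- y[lo:hi]
    m <- median(w)
    s <- 1.4826 * median(abs(w - m))
    med[i] <- m
    dev_ok[i] <- abs(y[i] - m) <= n_sigma * s
  }
  replaced <- which(!dev_ok)
  y[replaced] <- med[replaced]
  out <- curve
  out$intensity <- y
  meta <- curve_meta(curve)
  meta$replaced_points <- replaced
  set_curve_meta(out, meta)
}

#' Normalise a curve to its high-q window
#'
#' Divides intensity (and sigma) by the trapezoidal integral of intensity
#' over the open window `(q_lo, q_hi)`, the delay-invariant high-q region
#' dominated by local structure. After normalisation that integral equals 1,
#' so per-chamber illumination/volume scale factors cancel exactly; the
#' operation is idempotent and scale-invariant.
#'
#' @param curve An [scattering_curve()].
#' @param q_lo,q_hi Window bounds in inverse Angstrom (defaults 1.4, 1.6).
#' @return The normalised curve (metadata preserved, `norm_constant` added).
#' @export
normalize_curve <- function(curve, q_lo = 1.4, q_hi = 1.6) {
  inside <- curve$q > q_lo & curve$q < q_hi
  if (sum(inside) < 2L) {
    stop_sxl(sprintf(
      "normalisation window (%g, %g) needs >= 2 points but the curve covers [%g, %g] A^-1.",
      q_lo, q_hi, min(curve$q), max(curve$q)
    ), "sxl_qrange_error")
  }
  w <- trapz_weights(curve$q) * inside
  nc <- sum(w * curve$intensity)
  if (!is.finite(nc) || nc == 0) {
    stop_sxl("normalisation integral is zero or non-finite.", "sxl_qrange_error")
  }
  out <- curve
  out$intensity <- curve$intensity / nc
  out$sigma <- curve$sigma / abs(nc)
  meta <- curve_meta(curve)
  meta$norm_constant <- nc
  set_curve_meta(out, meta)
}

#' Guinier fit of the low-q region
#'
#' Iteratively self-consistent linear fit of `ln I` versus `q^2` over the
#' largest low-q window satisfying `q * Rg <= qRg_max`; the radius of
#' gyration is `Rg = sqrt(-3 * slope)` and the forward intensity
#' `I0 = exp(intercept)`. The fit is weighted by `(I/sigma)^2` — the inverse
#' variance of `ln I` — falling back to `I^2` (uniform absolute intensity
#' errors) when no uncertainties are available. A non-decaying Guinier
#' region (non-negative slope) raises a `sxl_non_guinier_error`.
#'
#' @param curve An [scattering_curve()] with positive intensities at low q.
#' @param qRg_max Self-consistent window cutoff (default 1.3, the classical
#'   globular-protein limit).
#' @param min_points Minimum points in the fit window.
#' @return List with `Rg` (Angstrom), `I0`, `q_window`, `n_points`,
#'   `n_iterations` and the `lm` fit object.
#' @export
guinier_fit <- function(curve, qRg_max = 1.3, min_points = 5L) {
  check_number(qRg_max, "qRg_max", positive = TRUE)
  pos <- curve$intensity > 0
  q <- curve$q[pos]
  y <- log(curve$intensity[pos])
  wt <- if (any(curve$sigma > 0)) {
    (curve$intensity[pos] / pmax(curve$sigma[pos], 1e-300))^2
  } else {
    curve$intensity[pos]^2
  }
  if (length(q) < min_points) {
    stop_sxl("too few positive-intensity points for a Guinier fit.", "sxl_non_guinier_error")
  }
  n_use <- max(min_points, min(length(q), 10L))
  prev <- -1L
  it <- 0L
  fit <- NULL
  repeat {
    it <- it + 1L
    idx <- seq_len(n_use)
    fit <- stats::lm(y[idx] ~ I(q[idx]^2), weights = wt[idx])
    slope <- coef(fit)[[2L]]
    if (slope >= 0) {
      stop_sxl("no Guinier decay: ln I does not decrease with q^2 at low q.",
               "sxl_non_guinier_error")
    }
    rg <- sqrt(-3 * slope)
    n_new <- max(min_points, sum(q * rg <= qRg_max))
    n_new <- min(n_new, length(q))
    if (n_new == n_use || n_new == prev || it >= 25L) {
      n_use <- n_new
      break
    }
    prev <- n_use
    n_use <- n_new
  }
  idx <- seq_len(n_use)
  fit <- stats::lm(y[idx] ~ I(q[idx]^2), weights = wt[idx])
  slope <- coef(fit)[[2L]]
  if (slope >= 0) {
    stop_sxl("no Guinier decay in the self-consistent window.", "sxl_non_guinier_error")
  }
  rg <- sqrt(-3 * slope)
  list(
    Rg = rg,
    I0 = exp(coef(fit)[[1L]]),
    q_window = c(q[1L], q[n_use]),
    n_points = n_use,
    n_iterations = it,
    fit = fit
  )
}

#' @export
autoplot.sxl_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$q, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q) (a.u.)")
}
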