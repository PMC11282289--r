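#' Difference scattering matrix
#'
#' The central object of kinetic analysis: difference signals
#' `dS(q, t)` on a common q grid, one column per pump-probe delay,
#' with per-column propagated uncertainties.
#'
#' @param q Strictly increasing q grid (inverse Angstrom).
#' @param delays Strictly increasing delays (seconds), one per column.
#' @param delta Matrix `length(q) x length(delays)` of difference signals.
#' @param sigma Matrix of the same shape with 1-sigma uncertainties
#'   (default 0).
#' @param n_kept,n_rejected Optional per-delay counts of averaged/rejected
#'   difference curves.
#' @return An object of class `sxl_diffmat`.
#' @export
difference_matrix <- function(q, delays, delta, sigma = NULL,
                              n_kept = NULL, n_rejected = NULL) {
  delta <- as.matrix(delta)
  if (is.unsorted(q, strictly = TRUE)) stop_sxl("q must be strictly increasing.", "sxl_grid_error")
  if (is.unsorted(delays, strictly = TRUE)) {
    stop_sxl("delays must be strictly increasing.", "sxl_invalid_parameter")
  }
  if (nrow(delta) != length(q) || ncol(delta) != length(delays)) {
    stop_sxl("delta must be length(q) x length(delays).", "sxl_invalid_parameter")
  }
  if (is.null(sigma)) sigma <- matrix(0, nrow(delta), ncol(delta))
  sigma <- as.matrix(sigma)
  stopifnot(all(dim(sigma) == dim(delta)))
  structure(
    list(
      q = as.numeric(q), delays = as.numeric(delays),
      delta = delta, sigma = sigma,
      n_kept = n_kept, n_rejected = n_rejected
    ),
    class = "sxl_diffmat"
  )
}

#' @export
print.sxl_diffmat <- function(x, ...) {
  cat(sprintf(
    "<sxl_diffmat> %d q points [%g, %g] A^-1 x %d delays [%.3g, %.3g] s\n",
    length(x$q), min(x$q), max(x$q), length(x$delays), min(x$delays), max(x$delays)
  ))
  invisible(x)
}

#' Restrict a difference matrix to q and delay windows
#'
#' @param dm An [difference_matrix()].
#' @param q_window,t_window Length-2 closed windows, or `NULL` to keep all.
#' @return The windowed `sxl_diffmat`.
#' @export
window_diffmat <- function(dm, q_window = NULL, t_window = NULL) {
  stopifnot(inherits(dm, "sxl_diffmat"))
  qi <- if (is.null(q_window)) rep(TRUE, length(dm$q)) else dm$q >= q_window[1L] & dm$q <= q_window[2L]
  ti <- if (is.null(t_window)) rep(TRUE, length(dm$delays)) else dm$delays >= t_window[1L] & dm$delays <= t_window[2L]
  if (!any(qi) || !any(ti)) {
    stop_sxl("requested window contains no data.", "sxl_window_error")
  }
  difference_matrix(
    dm$q[qi], dm$delays[ti],
    dm$delta[qi, ti, drop = FALSE], dm$sigma[qi, ti, drop = FALSE],
    n_kept = dm$n_kept[ti], n_rejected = dm$n_rejected[ti]
  )
}

#' @rdname difference_matrix
#' @param x An `sxl_diffmat`.
#' @param ... Unused.
#' @export
tidy.sxl_diffmat <- function(x, ...) {
  tibble(
    q = rep(x$q, times = length(x$delays)),
    delay = rep(x$delays, each = length(x$q)),
    delta = as.vector(x$delta),
    sigma = as.vector(x$sigma)
  )
}

#' @export
autoplot.sxl_diffmat <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$q, .data$delta,
                                  colour = factor(signif(.data$delay, 3)), group = .data$delay)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(q ~ (ring(A)^-1)), y = expression(Delta * S(q, t)),
      colour = "delay (s)"
    )
}
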