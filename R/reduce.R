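# Reduction of raw exposures to averaged difference curves. The hot path
# keeps all exposures as one intensity matrix (columns = exposures) so a
# full 1200-chamber chip reduces in milliseconds.

# Accept either an sxl_dataset or a list of sxl_curve on a shared grid and
# return the matrix-backed internal form.
as_exposure_set <- function(exposures, scheme = NULL) {
  if (inherits(exposures, "sxl_dataset")) {
    return(list(
      q = exposures$q, meta = exposures$exposures,
      intensity = exposures$intensity, sigma = exposures$sigma,
      scheme = scheme %||% exposures$scheme
    ))
  }
  stopifnot(is.list(exposures), length(exposures) > 0L)
  q <- exposures[[1L]]$q
  for (cv in exposures) {
    if (length(cv$q) != length(q) || any(cv$q != q)) {
      stop_sxl("all exposures must share one q grid.", "sxl_grid_error")
    }
  }
  meta <- purrr::map_dfr(seq_along(exposures), function(i) {
    m <- curve_meta(exposures[[i]])
    ch <- m$chamber %||% c(NA_integer_, NA_integer_)
    tibble(
      exposure = i,
      row = ch[1L], col = ch[2L],
      laser_state = m$laser_state %||% NA_character_,
      delay = m$delay %||% NA_real_
    )
  })
  if (identical(scheme, "dual")) {
    meta$pair_id <- sprintf("r%02dc%02d", meta$row, meta$col)
  } else {
    meta$pair_id <- sprintf("r%02dp%02d", meta$row, (meta$col + 1L) %/% 2L)
  }
  meta$delay_index <- match(meta$delay, sort(unique(meta$delay)))
  list(
    q = q, meta = meta,
    intensity = vapply(exposures, function(cv) cv$intensity, numeric(length(q))),
    sigma = vapply(exposures, function(cv) cv$sigma, numeric(length(q))),
    scheme = scheme
  )
}

#' Pair laser-off/on exposures and form difference curves
#'
#' Normalises every exposure to the high-q window, then subtracts
#' `normalize(on) - normalize(off)` per pair on the shared q grid, with
#' uncertainties propagated as the root sum of squares. Under dual probing a
#' pair is the two exposures of one chamber; under single probing the
#' off/on partners are adjacent columns in the same row. Missing partners
#' raise a pairing error listing the orphan chambers.
#'
#' @param exposures An `sxl_dataset` from [simulate_dataset()], or a list of
#'   [scattering_curve()]s carrying chamber/laser/delay metadata.
#' @param scheme `"dual"` or `"single"`; defaults to the dataset's scheme.
#' @param norm_window Normalisation window passed to the window integral
#'   (inverse Angstrom).
#' @param hampel Optional `c(window, n_sigma)`; when given, every exposure
#'   is despiked with [hampel_despike()] before normalisation.
#' @return An `sxl_dscollection`: shared `q`, a `pairs` tibble (pair id,
#'   chamber, delay) and `delta`/`sigma` matrices with one column per pair.
#' @export
pair_and_subtract <- function(exposures, scheme = NULL, norm_window = c(1.4, 1.6),
                              hampel = NULL) {
  es <- as_exposure_set(exposures, scheme)
  scheme <- es$scheme %||% "dual"
  q <- es$q
  I <- es$intensity
  S <- es$sigma
  if (!is.null(hampel)) {
    for (j in seq_len(ncol(I))) {
      cv <- hampel_despike(scattering_curve(q, I[, j], S[, j]),
                           window = hampel[1L], n_sigma = hampel[2L])
      I[, j] <- cv$intensity
    }
  }
  inside <- q > norm_window[1L] & q < norm_window[2L]
  if (sum(inside) < 2L) {
    stop_sxl(sprintf(
      "normalisation window (%g, %g) needs >= 2 points; q covers [%g, %g].",
      norm_window[1L], norm_window[2L], min(q), max(q)
    ), "sxl_qrange_error")
  }
  w <- trapz_weights(q) * inside
  nc <- as.numeric(crossprod(w, I))
  if (any(!is.finite(nc)) || any(nc == 0)) {
    stop_sxl("normalisation integral vanished for at least one exposure.", "sxl_qrange_error")
  }
  I <- sweep(I, 2L, nc, `/`)
  S <- sweep(S, 2L, abs(nc), `/`)

  meta <- es$meta
  meta$.col <- seq_len(nrow(meta))
  off <- meta[meta$laser_state == "off", ]
  on <- meta[meta$laser_state == "on", ]
  matched <- intersect(off$pair_id, on$pair_id)
  orphans <- setdiff(union(off$pair_id, on$pair_id), matched)
  if (length(orphans) > 0L) {
    orph <- meta[meta$pair_id %in% orphans, c("row", "col")]
    stop_sxl(sprintf(
      "unpaired exposures for %d chamber(s): %s",
      nrow(orph),
      paste(sprintf("(%d, %d)", orph$row, orph$col), collapse = ", ")
    ), "sxl_pairing_error")
  }
  off <- off[match(matched, off$pair_id), ]
  on <- on[match(matched, on$pair_id), ]
  delta <- I[, on$.col, drop = FALSE] - I[, off$.col, drop = FALSE]
  sig <- sqrt(S[, on$.col, drop = FALSE]^2 + S[, off$.col, drop = FALSE]^2)
  pairs <- tibble(
    pair_id = matched,
    row = on$row, col_on = on$col, col_off = off$col,
    delay = on$delay, delay_index = on$delay_index
  )
  ord <- order(pairs$delay_index, pairs$row, pairs$col_on)
  structure(
    list(
      q = q, pairs = pairs[ord, ],
      delta = delta[, ord, drop = FALSE], sigma = sig[, ord, drop = FALSE],
      scheme = scheme, norm_window = norm_window
    ),
    class = "sxl_dscollection"
  )
}

#' @export
print.sxl_dscollection <- function(x, ...) {
  cat(sprintf(
    "<sxl_dscollection> %d difference curves over %d delays (%s-probing)\n",
    nrow(x$pairs), length(unique(x$pairs$delay)), x$scheme
  ))
  invisible(x)
}

#' Average difference curves per delay with outlier rejection
#'
#' For each delay, curves whose RMS distance (over q, in units of the
#' per-point median sigma) from the pointwise median curve exceeds
#' `reject_n_sigma` are excluded, and the survivors averaged; the averaged
#' uncertainty is the root sum of squares of the kept sigmas divided by the
#' kept count (i.e. scales as 1/sqrt(n) for equal sigmas). When sigmas are
#' all zero (noise-free data) the robust scale of the deviations themselves
#' is used; exactly identical curves are never rejected.
#'
#' @param dss An `sxl_dscollection` from [pair_and_subtract()].
#' @param reject_n_sigma Rejection threshold (default 3).
#' @return An [difference_matrix()] with per-delay kept/rejected counts.
#' @export
average_by_delay <- function(dss, reject_n_sigma = 3) {
  stopifnot(inherits(dss, "sxl_dscollection"))
  check_number(reject_n_sigma, "reject_n_sigma", positive = TRUE)
  delays <- sort(unique(dss$pairs$delay))
  n_q <- length(dss$q)
  delta <- matrix(0, n_q, length(delays))
  sigma <- matrix(0, n_q, length(delays))
  n_kept <- integer(length(delays))
  n_rej <- integer(length(delays))
  for (di in seq_along(delays)) {
    cols <- which(dss$pairs$delay == delays[di])
    D <- dss$delta[, cols, drop = FALSE]
    Sg <- dss$sigma[, cols, drop = FALSE]
    if (ncol(D) > 1L) {
      med <- apply(D, 1L, median)
      scale_q <- apply(Sg, 1L, median)
      if (!any(scale_q > 0)) {
        scale_q <- 1.4826 * apply(abs(D - med), 1L, median)
      }
      usable <- scale_q > 0
      if (any(usable)) {
        dist <- sqrt(colMeans(((D[usable, , drop = FALSE] - med[usable]) /
                                 scale_q[usable])^2))
      } else {
        dist <- rep(0, ncol(D))
      }
      keep <- dist <= reject_n_sigma
    } else {
      keep <- TRUE
    }
    if (!any(keep)) {
      stop_sxl(sprintf(
        "all %d difference curves at delay %.3g s were rejected.",
        ncol(D), delays[di]
      ), "sxl_degenerate_delay")
    }
    nk <- sum(keep)
    delta[, di] <- rowMeans(D[, keep, drop = FALSE])
    sigma[, di] <- sqrt(rowSums(Sg[, keep, drop = FALSE]^2)) / nk
    n_kept[di] <- nk
    n_rej[di] <- sum(!keep)
  }
  difference_matrix(dss$q, delays, delta, sigma, n_kept = n_kept, n_rejected = n_rej)
}

#' Reduce a simulated or loaded dataset to a difference matrix
#'
#' Convenience chain: optional Hampel despiking, window normalisation,
#' pairing/subtraction and per-delay averaging, optionally restricted to an
#' analysis q window.
#'
#' @inheritParams pair_and_subtract
#' @inheritParams average_by_delay
#' @param q_window Optional final q window (inverse Angstrom).
#' @return An [difference_matrix()].
#' @export
reduce_dataset <- function(exposures, scheme = NULL, norm_window = c(1.4, 1.6),
                           hampel = NULL, reject_n_sigma = 3, q_window = NULL) {
  dss <- pair_and_subtract(exposures, scheme, norm_window, hampel)
  dm <- average_by_delay(dss, reject_n_sigma)
  if (!is.null(q_window)) dm <- window_diffmat(dm, q_window)
  dm
}
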