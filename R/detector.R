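#' Detector geometry for rendering and azimuthal integration
#'
#' Flat detector normal to the beam. A pixel at `(i, j)` (row, column,
#' 1-based centres) sits `r = pixel_size_mm * sqrt((i - cy)^2 + (j - cx)^2)`
#' from the beam centre, at scattering angle `theta = atan(r / distance)`
#' and momentum transfer `q = (4 pi / lambda) sin(theta / 2)`.
#'
#' @param beam_center Length-2 `c(x, y)` beam centre in pixel units.
#' @param pixel_size_mm Pixel pitch in millimetre.
#' @param distance_mm Sample-detector distance in millimetre.
#' @param wavelength_A X-ray wavelength in Angstrom (12 keV is ~1.033 A).
#' @return A `detector_geometry` object.
#' @export
detector_geometry <- function(beam_center, pixel_size_mm, distance_mm, wavelength_A) {
  stopifnot(length(beam_center) == 2L)
  check_number(pixel_size_mm, "pixel_size_mm", positive = TRUE)
  check_number(distance_mm, "distance_mm", positive = TRUE)
  check_number(wavelength_A, "wavelength_A", positive = TRUE)
  structure(
    list(
      beam_center = as.numeric(beam_center),
      pixel_size_mm = pixel_size_mm,
      distance_mm = distance_mm,
      wavelength_A = wavelength_A
    ),
    class = "detector_geometry"
  )
}

# q value of every pixel of an nrow x ncol image, as a matrix.
pixel_q_map <- function(geometry, shape) {
  stopifnot(inherits(geometry, "detector_geometry"))
  ny <- shape[1L]
  nx <- shape[2L]
  dy <- (seq_len(ny) - geometry$beam_center[2L])
  dx <- (seq_len(nx) - geometry$beam_center[1L])
  r_mm <- geometry$pixel_size_mm * sqrt(outer(dy^2, dx^2, `+`))
  theta <- atan(r_mm / geometry$distance_mm)
  (4 * pi / geometry$wavelength_A) * sin(theta / 2)
}

#' Render an isotropic detector image from a 1D curve
#'
#' Each pixel takes the curve value linearly interpolated at the pixel's q;
#' pixels whose q falls outside the curve's range are masked (`NA`). The
#' image is isotropic by construction (invariant under rotation about the
#' beam centre, up to pixelation).
#'
#' @param curve An [scattering_curve()].
#' @param geometry A [detector_geometry()].
#' @param shape Image shape `c(n_rows, n_cols)` in pixels.
#' @return List with `image` (matrix, masked pixels `NA`), `mask` (logical
#'   matrix, `TRUE` = usable) and the geometry.
#' @export
render_detector_image <- function(curve, geometry, shape) {
  qmap <- pixel_q_map(geometry, shape)
  inside <- qmap >= min(curve$q) & qmap <= max(curve$q)
  if (!any(inside)) {
    stop_sxl("geometry places no pixel inside the curve's q range.", "sxl_invalid_parameter")
  }
  img <- matrix(NA_real_, nrow(qmap), ncol(qmap))
  img[inside] <- approx(curve$q, curve$intensity, xout = qmap[inside])$y
  list(image = img, mask = inside, geometry = geometry)
}

#' Azimuthal integration of a detector image
#'
#' Bins pixels by their q value into half-open bins `[q_lo, q_hi)`; each
#' reported intensity is the mean of the unmasked pixel values in the bin,
#' the bin centre is the arithmetic midpoint of its edges, and the
#' uncertainty is the pixel standard deviation divided by the square root of
#' the pixel count. Empty bins are dropped.
#'
#' @param image Numeric matrix (or the list returned by
#'   [render_detector_image()]); `NA` pixels are treated as masked.
#' @param geometry A [detector_geometry()].
#' @param q_bins Number of equal-width bins over the unmasked q range, or an
#'   explicit vector of bin edges.
#' @param mask Optional logical matrix, `TRUE` = usable pixel.
#' @return An [scattering_curve()] with a `bin_count` column.
#' @export
azimuthal_integrate <- function(image, geometry, q_bins = 100L, mask = NULL) {
  if (is.list(image) && !is.null(image$image)) {
    if (is.null(mask)) mask <- image$mask
    image <- image$image
  }
  stopifnot(is.matrix(image))
  qmap <- pixel_q_map(geometry, dim(image))
  ok <- !is.na(image)
  if (!is.null(mask)) ok <- ok & mask
  if (!any(ok)) {
    stop_sxl("all pixels are masked: nothing to integrate.", "sxl_empty_integration")
  }
  qv <- qmap[ok]
  iv <- image[ok]
  edges <- if (length(q_bins) == 1L) {
    seq(min(qv), max(qv) * (1 + 1e-12), length.out = as.integer(q_bins) + 1L)
  } else {
    as.numeric(q_bins)
  }
  bin <- findInterval(qv, edges, rightmost.closed = FALSE, all.inside = FALSE)
  keep <- bin >= 1L & bin <= length(edges) - 1L
  qv <- qv[keep]
  iv <- iv[keep]
  bin <- bin[keep]
  if (length(bin) == 0L) {
    stop_sxl("no unmasked pixel falls inside the requested bins.", "sxl_empty_integration")
  }
  count <- tabulate(bin, nbins = length(edges) - 1L)
  sum_i <- unname(rowsum(iv, bin, reorder = TRUE))[, 1L]
  sum_i2 <- unname(rowsum(iv^2, bin, reorder = TRUE))[, 1L]
  present <- sort(unique(bin))
  mean_i <- sum_i / count[present]
  # unbiased per-bin pixel variance; single-pixel bins report sigma 0
  var_i <- pmax(sum_i2 - count[present] * mean_i^2, 0) / pmax(count[present] - 1L, 1L)
  sigma <- sqrt(var_i) / sqrt(count[present])
  centers <- (edges[-length(edges)] + edges[-1L]) / 2
  out <- scattering_curve(centers[present], mean_i, sigma)
  out$bin_count <- count[present]
  out
}
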