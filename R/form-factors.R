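#' Scattering model for a monomeric or dimeric globular species
#'
#' A minimal structural model used by the synthetic-data generator: a species
#' is either a homogeneous sphere of radius `radius` (monomer) or a rigid
#' pair of such spheres with centre-to-centre distance `center_distance`
#' (dimer). Spheres suffice to produce the qualitative difference-scattering
#' signatures of dissociation (negative low-q lobe) and association
#' (Guinier-region rise) with an exactly known ground truth; no atomistic
#' scattering is attempted.
#'
#' @param kind `"monomer-sphere"` or `"dimer-of-spheres"`.
#' @param radius Sphere radius in Angstrom, > 0.
#' @param center_distance Centre-to-centre distance in Angstrom for a dimer.
#'   Default `2.2 * radius`: slightly separated spheres, keeping a strong
#'   interference term while avoiding the degenerate touching case. Must be
#'   at least `2 * radius` (non-overlapping spheres).
#' @param contrast_volume Scattering amplitude of one sphere in arbitrary
#'   units; forward intensity of a monomer is `contrast_volume^2`.
#' @param species_name Label carried through to SADS bases and reports.
#' @return An object of class `scattering_model`.
#' @examples
#' dimer <- scattering_model("dimer-of-spheres", radius = 25)
#' monomer <- scattering_model("monomer-sphere", radius = 25)
#' @export
scattering_model <- function(kind = c("monomer-sphere", "dimer-of-spheres"),
                             radius,
                             center_distance = 2.2 * radius,
                             contrast_volume = 1,
                             species_name = kind) {
  kind <- match.arg(kind)
  check_number(radius, "radius", positive = TRUE)
  check_number(contrast_volume, "contrast_volume")
  if (kind == "dimer-of-spheres") {
    check_number(center_distance, "center_distance", positive = TRUE)
    if (center_distance < 2 * radius) {
      stop_sxl(sprintf(
        "center_distance (%g A) must be >= 2*radius (%g A): dimer spheres may not overlap.",
        center_distance, 2 * radius
      ), "sxl_invalid_parameter")
    }
  }
  structure(
    list(
      kind = kind, radius = radius,
      center_distance = if (kind == "dimer-of-spheres") center_distance else NA_real_,
      contrast_volume = contrast_volume,
      species_name = species_name
    ),
    class = "scattering_model"
  )
}

#' @export
print.scattering_model <- function(x, ...) {
  cat(sprintf(
    "<scattering_model> %s (%s): R = %g A%s, amplitude = %g\n",
    x$species_name, x$kind, x$radius,
    if (x$kind == "dimer-of-spheres") sprintf(", d = %g A", x$center_distance) else "",
    x$contrast_volume
  ))
  invisible(x)
}

#' Normalised sphere form factor P(q)
#'
#' The square of the normalised scattering amplitude of a homogeneous sphere,
#' `A(q) = 3 [sin(qR) - qR cos(qR)] / (qR)^3`, with `P(0) = 1`. The q -> 0
#' limit is handled analytically, so the curve is smooth through the origin.
#'
#' @param q Momentum transfer grid in inverse Angstrom, all >= 0.
#' @param radius Sphere radius in Angstrom, > 0.
#' @return Numeric vector `P(q)` in `[0, 1]`, same length as `q`.
#' @examples
#' q <- seq(0, 0.5, by = 0.01)
#' plot(q, sphere_form_factor(q, 30), type = "l", log = "")
#' @export
sphere_form_factor <- function(q, radius) {
  check_number(radius, "radius", positive = TRUE)
  if (any(q < 0)) stop_sxl("all q must be >= 0.", "sxl_invalid_parameter")
  sphere_amplitude(q, radius)^2
}

# Normalised sphere amplitude A(q); series expansion below x ~ 1e-2 where
# the closed form loses digits to cancellation (A = 1 - x^2/10 + x^4/280 - ...).
sphere_amplitude <- function(q, radius) {
  x <- q * radius
  a <- numeric(length(x))
  small <- x < 1e-2
  if (any(small)) {
    xs <- x[small]
    a[small] <- 1 - xs^2 / 10 + xs^4 / 280
  }
  if (any(!small)) {
    xl <- x[!small]
    a[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  }
  a
}

#' Solution scattering intensity of a model species
#'
#' Monomer: `I(q) = A^2 P(q)`. Dimer of spheres (Debye two-body term):
#' `I(q) = 2 A^2 P(q) [1 + sin(qd)/(qd)]`, with the q -> 0 limit
#' `sin(qd)/(qd) -> 1`, so the dimer's forward intensity is 4x the
#' monomer's (amplitude-squared doubling).
#'
#' @param model A [scattering_model()].
#' @param q Momentum transfer grid in inverse Angstrom.
#' @return Intensity vector in arbitrary units, same length as `q`.
#' @export
assembly_intensity <- function(model, q) {
  stopifnot(inherits(model, "scattering_model"))
  if (any(q < 0)) stop_sxl("all q must be >= 0.", "sxl_invalid_parameter")
  A <- model$contrast_volume^2
  P <- sphere_form_factor(q, model$radius)
  if (model$kind == "monomer-sphere") {
    A * P
  } else {
    d <- model$center_distance
    if (!is.finite(d) || d <= 0) {
      stop_sxl("dimer center_distance must be > 0.", "sxl_invalid_parameter")
    }
    2 * A * P * (1 + sinc(q * d))
  }
}

# sin(x)/x with the x -> 0 limit 1.
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-8
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

#' Species-associated difference scattering (SADS) basis
#'
#' Builds the matrix of pure difference signals `SADS_i(q) =
#' I_intermediate_i(q) - I_ground(q)` for a set of intermediates relative to
#' a common ground state. For a dimer ground state dissociating into two free
#' monomers the forward (q -> 0) value is negative; for monomer -> dimer
#' association it is positive.
#'
#' By default each column is expressed in the gauge fixed by the high-q
#' normalisation window: the component proportional to the ground-state curve
#' inside `gauge_window` is projected out
#' (`SADS_i <- SADS_i - g * int_win(SADS_i) / int_win(g)`). After on/off
#' curves are normalised to that window, a ground-curve-proportional
#' component inside it is unobservable, so this gauge makes the generated
#' truth exactly what the reduction chain can recover. Set
#' `gauge_window = NULL` for raw differences.
#'
#' @param ground [scattering_model()] of the ground state.
#' @param intermediates List of [scattering_model()]s, one per transient
#'   species, in kinetic order.
#' @param q Shared momentum-transfer grid (inverse Angstrom), strictly
#'   increasing.
#' @param gauge_window Length-2 numeric window (inverse Angstrom) or `NULL`.
#' @return A `sads_basis`: list with `q`, matrix `sads` (length(q) x
#'   n species), `species` labels and the ground intensity `ground`.
#' @export
make_sads_basis <- function(ground, intermediates, q, gauge_window = c(1.4, 1.6)) {
  stopifnot(inherits(ground, "scattering_model"))
  if (inherits(intermediates, "scattering_model")) intermediates <- list(intermediates)
  if (length(intermediates) < 1L) {
    stop_sxl("need at least one intermediate species.", "sxl_invalid_parameter")
  }
  if (is.unsorted(q, strictly = TRUE)) {
    stop_sxl("q grid must be strictly increasing.", "sxl_grid_error")
  }
  g <- assembly_intensity(ground, q)
  sads <- vapply(intermediates, function(m) assembly_intensity(m, q) - g, numeric(length(q)))
  sads <- matrix(sads, nrow = length(q))
  if (!is.null(gauge_window)) {
    w <- trapz_weights(q) * (q > gauge_window[1L] & q < gauge_window[2L])
    ng <- sum(w * g)
    if (ng <= 0) {
      stop_sxl("gauge window carries no ground-state intensity on this q grid.", "sxl_grid_error")
    }
    coef <- as.numeric(crossprod(w, sads)) / ng
    sads <- sads - outer(g, coef)
  }
  structure(
    list(
      q = q, sads = sads,
      species = vapply(intermediates, function(m) m$species_name, character(1L)),
      ground = g
    ),
    class = "sads_basis"
  )
}

#' @export
print.sads_basis <- function(x, ...) {
  cat(sprintf(
    "<sads_basis> %d species (%s) on %d q points [%g, %g] A^-1\n",
    ncol(x$sads), paste(x$species, collapse = " -> "),
    length(x$q), min(x$q), max(x$q)
  ))
  invisible(x)
}

#' @rdname make_sads_basis
#' @param x A `sads_basis`.
#' @param ... Unused.
#' @export
tidy.sads_basis <- function(x, ...) {
  tibble(
    q = rep(x$q, times = ncol(x$sads)),
    species = rep(x$species, each = length(x$q)),
    sads = as.vector(x$sads)
  )
}

#' @export
autoplot.sads_basis <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$q, .data$sads, colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(q ~ (ring(A)^-1)), y = expression(Delta * S(q)),
      colour = "species"
    )
}
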