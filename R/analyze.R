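#' Default synthetic reaction bases
#'
#' Ready-made SADS bases emulating the two photoreaction archetypes the
#' chip-based pipeline is designed to resolve:
#'
#' * `default_dissociation_basis()` — a homodimer ground state that passes
#'   through a slightly expanded dimeric intermediate before dissociating
#'   into two free monomers and relaxing into the final monomeric product;
#'   its difference signals carry the canonical negative low-q lobe.
#' * `default_association_basis()` — a monomeric ground state that, after a
#'   small local perturbation, dimerises; its product difference signal
#'   rises in the Guinier region.
#'
#' @param q Momentum-transfer grid, inverse Angstrom (default 240 points,
#'   0.01-1.8, covering both the 0.03-1.0 analysis window and the 1.4-1.6
#'   normalisation window).
#' @param radius Sphere radius of the protomer in Angstrom.
#' @param contrast_volume Amplitude of one protomer.
#' @return A `sads_basis` with three transient species `I1 -> I2 -> P`.
#' @export
default_dissociation_basis <- function(q = default_q_grid(), radius = 25,
                                       contrast_volume = 1) {
  ground <- scattering_model("dimer-of-spheres", radius = radius,
                             contrast_volume = contrast_volume,
                             species_name = "dimer-ground")
  # I1: expanded dimer; I2: two free monomers (amplitude doubled so the
  # forward intensity is 2 A^2, half the dimer's 4 A^2); P: monomer after a
  # further small conformational change
  i1 <- scattering_model("dimer-of-spheres", radius = radius,
                         center_distance = 2.6 * radius,
                         contrast_volume = contrast_volume, species_name = "I1")
  i2 <- scattering_model("monomer-sphere", radius = radius,
                         contrast_volume = sqrt(2) * contrast_volume,
                         species_name = "I2")
  p <- scattering_model("monomer-sphere", radius = 1.06 * radius,
                        contrast_volume = sqrt(2) * contrast_volume,
                        species_name = "P")
  make_sads_basis(ground, list(i1, i2, p), q)
}

#' @rdname default_dissociation_basis
#' @export
default_association_basis <- function(q = default_q_grid(), radius = 22,
                                      contrast_volume = 1) {
  ground <- scattering_model("monomer-sphere", radius = radius,
                             contrast_volume = contrast_volume,
                             species_name = "monomer-ground")
  i1 <- scattering_model("monomer-sphere", radius = 1.03 * radius,
                         contrast_volume = contrast_volume, species_name = "I1")
  i2 <- scattering_model("monomer-sphere", radius = 1.08 * radius,
                         contrast_volume = contrast_volume, species_name = "I2")
  p <- scattering_model("dimer-of-spheres", radius = radius,
                        contrast_volume = contrast_volume, species_name = "P")
  make_sads_basis(ground, list(i1, i2, p), q)
}

#' @rdname default_dissociation_basis
#' @param n_points Grid size.
#' @param q_min,q_max Grid extent (inverse Angstrom).
#' @export
default_q_grid <- function(q_min = 0.01, q_max = 1.8, n_points = 240L) {
  seq(q_min, q_max, length.out = n_points)
}

#' Full kinetic analysis of a difference matrix
#'
#' The standard analysis chain: SVD of the windowed matrix, significance
#' selection, multi-exponential fit of the first significant right singular
#' vector, construction of a sequential kinetic model from the fitted time
#' constants, kinetics-constrained SADS extraction, and (optionally)
#' refinement of the rate constants against the full matrix.
#'
#' @param dm An [difference_matrix()].
#' @param q_window,t_window Analysis windows (defaults: q 0.03-1.0 inverse
#'   Angstrom, all delays).
#' @param n_species Number of transient species; defaults to the number of
#'   significant SVD components (minimum 2).
#' @param n_exp Exponentials in the RSV fit; defaults to `n_species - 1`.
#' @param refine Refine rates by residual minimisation (default `TRUE`).
#' @param recovery_rate Optional ground-state recovery rate passed to the
#'   kinetic model.
#' @param ... Passed to [select_significant()].
#' @return An `sxl_analysis` bundling `svd`, `selection`, `rsv_fit`,
#'   `model`, `kca` and (when refined) `refinement`.
#' @export
analyze_diffmat <- function(dm, q_window = c(0.03, 1.0), t_window = NULL,
                            n_species = NULL, n_exp = NULL, refine = TRUE,
                            recovery_rate = NULL, ...) {
  sv <- svd_analysis(dm, q_window, t_window)
  sel <- select_significant(sv, ...)
  n_species <- n_species %||% max(sel$n_significant, 2L)
  n_exp <- n_exp %||% (n_species - 1L)
  first_sig <- which(sel$diagnostics$significant)[1L]
  if (is.na(first_sig)) first_sig <- 1L
  fit <- fit_rsv_exponentials(sv$delays, sv$v[, first_sig], n_exp = n_exp)
  model <- kinetic_model(tau = fit$tau, recovery_rate = recovery_rate)
  dmw <- window_diffmat(dm, q_window, t_window)
  kca <- kca_extract_sads(dmw, model)
  refinement <- NULL
  if (refine) {
    refinement <- refine_rates(dmw, model)
    model <- refinement$model
    kca <- refinement$kca
  }
  structure(
    list(
      svd = sv, selection = sel, rsv_fit = fit,
      model = model, kca = kca, refinement = refinement,
      q_window = q_window, t_window = t_window
    ),
    class = "sxl_analysis"
  )
}

#' @export
print.sxl_analysis <- function(x, ...) {
  cat(sprintf(
    "<sxl_analysis> %d significant component(s); tau = %s s; KCA residual %.4g\n",
    x$selection$n_significant,
    paste(signif(x$model$tau, 3), collapse = ", "),
    x$kca$residual
  ))
  invisible(x)
}

#' @rdname analyze_diffmat
#' @param x An `sxl_analysis`.
#' @param ... Unused.
#' @export
glance.sxl_analysis <- function(x, ...) {
  tibble(
    n_significant = x$selection$n_significant,
    n_species = length(x$model$species),
    tau = list(x$model$tau),
    tau_se = list(x$rsv_fit$tau_se),
    residual_rms = x$kca$residual,
    refined = !is.null(x$refinement) && x$refinement$converged
  )
}
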