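#' Shot-noise model for simulated exposures
#'
#' Gaussian heteroscedastic noise on azimuthally averaged curves:
#' `sigma(q) = relative_sigma * I(q) + floor`, plus an optional per-chamber
#' multiplicative scale jitter shared by both exposures of a chamber (the
#' illumination/volume variation that window normalisation removes).
#'
#' @param relative_sigma Fractional per-point noise level (>= 0).
#' @param floor Additive noise floor in intensity units.
#' @param chamber_jitter Fractional standard deviation of the per-chamber
#'   scale factor.
#' @param seed Integer seed; an identical seed reproduces a dataset
#'   bit-exactly.
#' @return A `noise_model` object.
#' @export
noise_model <- function(relative_sigma = 0.02, floor = 0, chamber_jitter = 0, seed = NULL) {
  check_number(relative_sigma, "relative_sigma", non_negative = TRUE)
  check_number(floor, "floor", non_negative = TRUE)
  check_number(chamber_jitter, "chamber_jitter", non_negative = TRUE)
  structure(
    list(relative_sigma = relative_sigma, floor = floor,
         chamber_jitter = chamber_jitter, seed = seed),
    class = "noise_model"
  )
}

#' Simulate a full SXL chip dataset with known ground truth
#'
#' Generates every exposure of an exposure plan: for each chamber the
#' laser-off curve is the ground-state intensity and the laser-on curve at
#' delay `t` is `ground + sum_i SADS_i(q) * P_i(t)`, both scaled by the
#' chamber's jitter factor and perturbed by the noise model. The returned
#' object carries a ground-truth record (SADS in normalised units,
#' populations, rate constants, seed) kept separate from the data path so
#' recovery tests never read truth from the pipeline's inputs.
#'
#' @param layout A [chip_layout()].
#' @param plan An exposure plan from [allocate_chambers()]; its delays define
#'   the time axis.
#' @param sads A `sads_basis` from [make_sads_basis()].
#' @param model A [kinetic_model()] with `length(species) == ncol(sads$sads) + 1`
#'   ground-excluded species... i.e. one SADS column per transient species
#'   (intermediates and product).
#' @param noise A [noise_model()].
#' @return An `sxl_dataset`: shared `q`, an `exposures` tibble (exposure
#'   index, chamber, laser state, delay), intensity and sigma matrices with
#'   one column per exposure, and the `truth` record.
#' @export
simulate_dataset <- function(layout, plan, sads, model, noise = noise_model()) {
  stopifnot(
    inherits(layout, "chip_layout"), inherits(plan, "exposure_plan"),
    inherits(sads, "sads_basis"), inherits(model, "kinetic_model")
  )
  n_transient <- length(model$species)
  if (ncol(sads$sads) != n_transient) {
    stop_sxl(sprintf(
      "SADS basis has %d species but the kinetic model defines %d.",
      ncol(sads$sads), n_transient
    ), "sxl_invalid_parameter")
  }
  rows_needed <- length(plan$delays) * plan$rows_per_delay
  if (rows_needed > layout$n_rows) {
    stop_sxl(sprintf(
      "plan needs %d rows but chip has %d: short by %d.",
      rows_needed, layout$n_rows, rows_needed - layout$n_rows
    ), "sxl_capacity_error")
  }
  if (max(plan$chambers$col) > layout$n_cols) {
    stop_sxl(sprintf(
      "plan addresses column %d but chip has only %d columns.",
      max(plan$chambers$col), layout$n_cols
    ), "sxl_capacity_error")
  }
  if (!is.null(noise$seed)) set.seed(noise$seed)

  q <- sads$q
  g <- sads$ground
  P <- population_matrix(model, plan$delays)          # t x species
  excited <- sads$sads %*% t(P)                        # q x t: sum_i SADS_i P_i(t)

  ch <- plan$chambers
  n_ch <- nrow(ch)
  scale <- 1 + noise$chamber_jitter * rnorm(n_ch)

  if (plan$scheme == "dual") {
    exposures <- tibble(
      exposure = seq_len(2L * n_ch),
      pair_id = rep(ch$pair_id, each = 2L),
      row = rep(ch$row, each = 2L),
      col = rep(ch$col, each = 2L),
      laser_state = rep(c("off", "on"), times = n_ch),
      delay = rep(ch$delay, each = 2L),
      delay_index = rep(ch$delay_index, each = 2L),
      scale = rep(scale, each = 2L)
    )
  } else {
    exposures <- tibble(
      exposure = seq_len(n_ch),
      pair_id = ch$pair_id,
      row = ch$row, col = ch$col,
      laser_state = ifelse(ch$role == "off", "off", "on"),
      delay = ch$delay, delay_index = ch$delay_index,
      scale = scale
    )
  }
  on <- exposures$laser_state == "on"
  ideal <- matrix(g, length(q), nrow(exposures))
  ideal[, on] <- ideal[, on] + excited[, exposures$delay_index[on], drop = FALSE]
  ideal <- sweep(ideal, 2L, exposures$scale, `*`)
  sigma <- noise$relative_sigma * abs(ideal) + noise$floor
  intensity <- ideal
  if (noise$relative_sigma > 0 || noise$floor > 0) {
    intensity <- intensity + matrix(rnorm(length(ideal)), nrow(ideal)) * sigma
  }

  norm_w <- trapz_weights(q) * (q > 1.4 & q < 1.6)
  n_ground <- sum(norm_w * g)
  truth <- list(
    species = model$species,
    rates = model$rates, tau = model$tau, phi = model$phi,
    delays = plan$delays,
    sads_raw = sads$sads,
    # truth on the scale the reduction chain produces: curves are
    # normalised to unit integral over (1.4, 1.6), so the recoverable
    # SADS is the raw SADS divided by the ground-state window integral
    sads_norm = sads$sads / n_ground,
    populations = P,
    ground = g,
    norm_constant = n_ground,
    seed = noise$seed,
    noise = noise[c("relative_sigma", "floor", "chamber_jitter")]
  )
  structure(
    list(
      q = q, exposures = exposures,
      intensity = intensity, sigma = sigma,
      scheme = plan$scheme, layout = layout, plan = plan,
      truth = truth
    ),
    class = "sxl_dataset"
  )
}

#' @export
print.sxl_dataset <- function(x, ...) {
  cat(sprintf(
    "<sxl_dataset> %s-probing, %d exposures (%d chambers), %d q points, %d delays\n",
    x$scheme, nrow(x$exposures), length(unique(paste(x$exposures$row, x$exposures$col))),
    length(x$q), length(unique(x$exposures$delay))
  ))
  invisible(x)
}

#' Extract one exposure as a scattering curve
#'
#' @param dataset An `sxl_dataset`.
#' @param i Exposure index.
#' @return An [scattering_curve()].
#' @export
dataset_curve <- function(dataset, i) {
  stopifnot(inherits(dataset, "sxl_dataset"))
  e <- dataset$exposures[i, ]
  scattering_curve(
    dataset$q, dataset$intensity[, i], dataset$sigma[, i],
    chamber = c(e$row, e$col), laser_state = e$laser_state,
    delay = e$delay, exposure_index = e$exposure
  )
}

#' @export
as_tibble.sxl_dataset <- function(x, ...) {
  out <- x$exposures
  out$curve <- purrr::map(out$exposure, function(i) dataset_curve(x, i))
  out
}

#' Simulate repeated pump-probe measurements of a capillary sample
#'
#' In a closed capillary the same sample volume is re-exposed, so an
#' irreversible fraction `damage_fraction_per_shot` of the active population
#' is lost per repetition and converted to a damaged, non-photoactive
#' species whose scattering adds a low-q aggregation term. The difference
#' signal at repetition `r` (r = 0, 1, ...) therefore scales as
#' `(1 - f)^r`, while the static Guinier-region intensity grows
#' monotonically when `aggregation_scale > 0`.
#'
#' @param sads A `sads_basis`; its last species' SADS is taken as the probed
#'   difference signal and its ground curve as the static pattern.
#' @param n_repeats Number of repetitions (>= 1).
#' @param damage_fraction_per_shot Fraction of active sample lost per shot,
#'   in \[0, 1\].
#' @param aggregation_scale Forward-intensity amplitude of the aggregate
#'   term per unit damaged fraction.
#' @param aggregate_rg Radius of gyration of the aggregate term (Angstrom).
#' @return List with `q`, a `summary` tibble (repetition, ds_amplitude
#'   relative to r = 0, guinier intensity), and `static` / `ds` matrices
#'   (one column per repetition).
#' @export
simulate_capillary_series <- function(sads, n_repeats,
                                      damage_fraction_per_shot = 0.2,
                                      aggregation_scale = 0,
                                      aggregate_rg = 150) {
  stopifnot(inherits(sads, "sads_basis"))
  check_number(n_repeats, "n_repeats", positive = TRUE)
  check_number(damage_fraction_per_shot, "damage_fraction_per_shot", non_negative = TRUE)
  if (damage_fraction_per_shot > 1) {
    stop_sxl("damage_fraction_per_shot must be in [0, 1].", "sxl_invalid_parameter")
  }
  check_number(aggregation_scale, "aggregation_scale", non_negative = TRUE)
  n_repeats <- as.integer(n_repeats)
  q <- sads$q
  ds0 <- sads$sads[, ncol(sads$sads)]
  agg <- exp(-q^2 * aggregate_rg^2 / 3)
  reps <- seq_len(n_repeats) - 1L
  active <- (1 - damage_fraction_per_shot)^reps
  damaged <- 1 - active
  ds <- outer(ds0, active)
  static <- outer(sads$ground, rep(1, n_repeats)) +
    outer(aggregation_scale * agg, damaged)
  summary <- tibble(
    repetition = reps,
    active_fraction = active,
    ds_amplitude = active,
    guinier_intensity = static[1L, ]
  )
  list(q = q, summary = summary, static = static, ds = ds)
}
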