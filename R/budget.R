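# Sample- and photon-budget arithmetic for fixed-target vs capillary
# measurements. All quantities are exact arithmetic on their inputs;
# 2-significant-figure rounding is for report strings only and never feeds
# back into computation.

#' Sample budget of a measurement campaign
#'
#' @param total_mass_ug Total protein consumed, in micrograms.
#' @param n_ds Number of difference scattering curves (DSs) obtained. One DS
#'   is one averaged difference curve per (delay, repeat).
#' @param n_chambers Optional number of microchambers the mass was spread over.
#' @return A `sample_budget` with exact `per_ds_mass_ug` (and
#'   `per_chamber_mass_ng` when `n_chambers` is given) plus 2-significant-
#'   figure report values.
#' @examples
#' sample_budget(115, 30)$per_ds_mass_ug_report # 3.8
#' @export
sample_budget <- function(total_mass_ug, n_ds, n_chambers = NULL) {
  check_number(total_mass_ug, "total_mass_ug", non_negative = TRUE)
  check_number(n_ds, "n_ds", positive = TRUE)
  per_ds <- total_mass_ug / n_ds
  per_chamber <- NULL
  if (!is.null(n_chambers)) {
    check_number(n_chambers, "n_chambers", positive = TRUE)
    per_chamber <- 1e3 * total_mass_ug / n_chambers
  }
  structure(
    list(
      total_mass_ug = total_mass_ug,
      n_ds = n_ds,
      n_chambers = n_chambers,
      per_ds_mass_ug = per_ds,
      per_ds_mass_ug_report = round_signif(per_ds),
      per_chamber_mass_ng = per_chamber,
      per_chamber_mass_ng_report = if (is.null(per_chamber)) NULL else round_signif(per_chamber)
    ),
    class = "sample_budget"
  )
}

#' @export
print.sample_budget <- function(x, ...) {
  cat(sprintf(
    "<sample_budget> %g ug over %g DSs -> %g ug/DS%s\n",
    x$total_mass_ug, x$n_ds, x$per_ds_mass_ug_report,
    if (is.null(x$per_chamber_mass_ng)) "" else sprintf(" (%g ng/chamber)", x$per_chamber_mass_ng_report)
  ))
  invisible(x)
}

#' Sample mass per difference scattering curve
#'
#' @inheritParams sample_budget
#' @return List with the exact quotient `value` (ug per DS) and its
#'   2-significant-figure `report`.
#' @examples
#' mass_per_ds(115, 30)$report # 3.8
#' mass_per_ds(390, 4)$value   # 97.5
#' @export
mass_per_ds <- function(total_mass_ug, n_ds) {
  b <- sample_budget(total_mass_ug, n_ds)
  list(value = b$per_ds_mass_ug, report = b$per_ds_mass_ug_report)
}

#' Sample mass per microchamber and for chamber subsets
#'
#' @param total_mass_ug Total mass loaded on the chip, micrograms.
#' @param layout A [chip_layout()].
#' @param subset_sizes Optional chamber counts for which subset masses are
#'   reported (in micrograms).
#' @return List with `per_chamber_ng` (exact and report) and a tibble of
#'   subset masses.
#' @examples
#' per_chamber_mass(38, chip_layout(), subset_sizes = c(80, 40))
#' @export
per_chamber_mass <- function(total_mass_ug, layout, subset_sizes = integer()) {
  stopifnot(inherits(layout, "chip_layout"))
  check_number(total_mass_ug, "total_mass_ug", non_negative = TRUE)
  if (layout$n_chambers < 1L) {
    stop_sxl("layout has no chambers.", "sxl_invalid_parameter")
  }
  per_ng <- 1e3 * total_mass_ug / layout$n_chambers
  subsets <- tibble(
    n_chambers = as.integer(subset_sizes),
    mass_ug = per_ng * subset_sizes / 1e3,
    mass_ug_report = round_signif(per_ng * subset_sizes / 1e3)
  )
  list(
    per_chamber_ng = per_ng,
    per_chamber_ng_report = round_signif(per_ng),
    subsets = subsets
  )
}

#' Photon budget of an X-ray pulse train
#'
#' @param photons_per_pulse Photons delivered by one isolated X-ray pulse.
#' @param n_pulses Number of pulses in the train.
#' @return Total photons (exact product).
#' @examples
#' photon_budget(3e9, 11) # 3.3e10
#' photon_budget(3e9, 24) # 7.2e10
#' @export
photon_budget <- function(photons_per_pulse, n_pulses) {
  check_number(photons_per_pulse, "photons_per_pulse", non_negative = TRUE)
  check_number(n_pulses, "n_pulses", non_negative = TRUE)
  photons_per_pulse * n_pulses
}

#' Sample-utilisation efficiency ratio between two budgets
#'
#' Ratio of per-DS sample mass of budget `b` to budget `a`; values > 1 mean
#' `a` is the more sample-efficient setup.
#'
#' @param budget_a,budget_b [sample_budget()]s (typically fixed-target chip
#'   vs capillary).
#' @return List with the exact `ratio` and its 2-significant-figure `report`.
#' @examples
#' sxl <- sample_budget(115, 30)       # 3.8 ug/DS
#' cap <- sample_budget(373, 1)        # 373 ug/DS
#' efficiency_ratio(sxl, cap)$report   # ~98, i.e. "about 100x"
#' @export
efficiency_ratio <- function(budget_a, budget_b) {
  stopifnot(inherits(budget_a, "sample_budget"), inherits(budget_b, "sample_budget"))
  if (budget_a$per_ds_mass_ug <= 0 || budget_b$per_ds_mass_ug <= 0) {
    stop_sxl("per-DS masses must be positive to form a ratio.", "sxl_invalid_parameter")
  }
  r <- budget_b$per_ds_mass_ug / budget_a$per_ds_mass_ug
  list(ratio = r, report = round_signif(r))
}

#' Budget summary table for a measurement plan
#'
#' Convenience wrapper combining chip, plan and pulse-train arithmetic into
#' one tidy table (the CLI `budget` subcommand prints this).
#'
#' @param layout A [chip_layout()].
#' @param plan An `exposure_plan` from [allocate_chambers()].
#' @param photons_per_pulse,n_pulses Optional pulse-train description.
#' @return A tibble of named quantities with exact values and report values.
#' @export
budget_table <- function(layout, plan, photons_per_pulse = NULL, n_pulses = NULL) {
  stopifnot(inherits(layout, "chip_layout"), inherits(plan, "exposure_plan"))
  total_ug <- layout$per_chamber_mass_ng * plan$n_chambers_used / 1e3
  rows <- tibble(
    quantity = c(
      "chambers_per_delay", "chambers_used", "rows_remaining",
      "per_chamber_mass_ng", "mass_used_ug"
    ),
    value = c(
      plan$chambers_per_delay, plan$n_chambers_used, plan$rows_remaining,
      layout$per_chamber_mass_ng, total_ug
    )
  )
  if (!is.null(photons_per_pulse) && !is.null(n_pulses)) {
    rows <- bind_rows(rows, tibble(
      quantity = "photons_per_train",
      value = photon_budget(photons_per_pulse, n_pulses)
    ))
  }
  rows$report <- round_signif(rows$value)
  rows
}
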