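#' Fixed-target SXL chip layout
#'
#' Describes the microchamber grid of a serial X-ray liquidography chip and
#' the sample it carries. The default 40 columns x 30 rows grid with 4 nl
#' chambers at 0.1 mM of a ~79 kDa dimeric photoreceptor holds about 38 ug
#' of protein in total, i.e. about 32 ng per chamber.
#'
#' @param n_rows,n_cols Grid dimensions (rows are consumed delay by delay;
#'   each row holds `n_cols` chambers).
#' @param chamber_volume_nl Chamber volume in nanolitre.
#' @param sample_concentration_M Protein concentration in mol/l.
#' @param molecular_weight Molar mass in g/mol.
#' @return A `chip_layout` object.
#' @examples
#' chip <- chip_layout()
#' chip$n_chambers          # 1200
#' chip$per_chamber_mass_ng # ~32
#' @export
chip_layout <- function(n_rows = 30L, n_cols = 40L,
                        chamber_volume_nl = 4,
                        sample_concentration_M = 1e-4,
                        molecular_weight = 7.9e4) {
  check_number(n_rows, "n_rows", positive = TRUE)
  check_number(n_cols, "n_cols", positive = TRUE)
  check_number(chamber_volume_nl, "chamber_volume_nl", non_negative = TRUE)
  check_number(sample_concentration_M, "sample_concentration_M", non_negative = TRUE)
  check_number(molecular_weight, "molecular_weight", non_negative = TRUE)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  # mass per chamber: V [l] * c [mol/l] * M [g/mol], reported in ng
  per_chamber_ng <- chamber_volume_nl * 1e-9 * sample_concentration_M * molecular_weight * 1e9
  structure(
    list(
      n_rows = n_rows, n_cols = n_cols,
      n_chambers = n_rows * n_cols,
      chamber_volume_nl = chamber_volume_nl,
      sample_concentration_M = sample_concentration_M,
      molecular_weight = molecular_weight,
      per_chamber_mass_ng = per_chamber_ng,
      total_mass_ug = per_chamber_ng * n_rows * n_cols / 1e3
    ),
    class = "chip_layout"
  )
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf(
    "<chip_layout> %d x %d chambers (%d), %g nl each, %.3g ng/chamber, %.3g ug total\n",
    x$n_cols, x$n_rows, x$n_chambers, x$chamber_volume_nl,
    x$per_chamber_mass_ng, x$total_mass_ug
  ))
  invisible(x)
}

#' Allocate chip rows to time delays and build the exposure plan
#'
#' Assigns `rows_per_delay` consecutive rows to each pump-probe delay and
#' orders the chambers in the raster ("zigzag") sequence the stage follows:
#' odd rows left-to-right, even rows right-to-left. Under the dual-probing
#' scheme each chamber receives exactly two X-ray exposures (laser-off, then
#' laser-on at its delay); under single-probing each chamber is exposed once
#' and off/on partners are adjacent columns in the same row (columns 1/2,
#' 3/4, ...; `n_cols` must be even).
#'
#' @param layout A [chip_layout()].
#' @param delays Numeric vector of pump-probe delays in seconds.
#' @param rows_per_delay Rows consumed per delay (default 3, i.e. 120
#'   chambers per delay on the standard chip).
#' @param scheme `"dual"` or `"single"` probing.
#' @return An `exposure_plan`: the chamber assignment tibble plus a
#'   consumption summary (chambers per delay, rows consumed/remaining).
#' @examples
#' plan <- allocate_chambers(chip_layout(), delay_grid("half-decade"), 3)
#' plan$chambers_per_delay # 120
#' plan$rows_remaining     # 0
#' @export
allocate_chambers <- function(layout, delays, rows_per_delay = 3L,
                              scheme = c("dual", "single")) {
  stopifnot(inherits(layout, "chip_layout"))
  scheme <- match.arg(scheme)
  check_number(rows_per_delay, "rows_per_delay", positive = TRUE)
  rows_per_delay <- as.integer(rows_per_delay)
  if (length(delays) < 1L || any(!is.finite(delays)) || any(delays < 0)) {
    stop_sxl("delays must be non-negative finite times in seconds.", "sxl_invalid_parameter")
  }
  if (is.unsorted(delays, strictly = TRUE)) {
    stop_sxl("delays must be strictly increasing.", "sxl_invalid_parameter")
  }
  if (scheme == "single" && layout$n_cols %% 2L != 0L) {
    stop_sxl("single-probing pairing needs an even number of columns.", "sxl_invalid_parameter")
  }
  rows_needed <- length(delays) * rows_per_delay
  if (rows_needed > layout$n_rows) {
    stop_sxl(sprintf(
      "plan needs %d rows (%d delays x %d rows/delay) but the chip has %d: short by %d rows.",
      rows_needed, length(delays), rows_per_delay, layout$n_rows, rows_needed - layout$n_rows
    ), "sxl_capacity_error")
  }
  row_idx <- seq_len(rows_needed)
  chambers <- purrr::map_dfr(row_idx, function(r) {
    cols <- if (r %% 2L == 1L) seq_len(layout$n_cols) else rev(seq_len(layout$n_cols))
    tibble(row = r, col = cols)
  })
  chambers$delay_index <- ((chambers$row - 1L) %/% rows_per_delay) + 1L
  chambers$delay <- delays[chambers$delay_index]
  chambers$chamber_id <- sprintf("r%02dc%02d", chambers$row, chambers$col)
  if (scheme == "single") {
    # partner chambers: within a row, odd/even column pairs; the
    # lower column of each pair takes the laser-off exposure
    chambers$role <- ifelse(chambers$col %% 2L == 1L, "off", "on")
    chambers$pair_id <- sprintf("r%02dp%02d", chambers$row, (chambers$col + 1L) %/% 2L)
  } else {
    chambers$role <- "both"
    chambers$pair_id <- chambers$chamber_id
  }
  structure(
    list(
      scheme = scheme,
      delays = delays,
      rows_per_delay = rows_per_delay,
      chambers = chambers,
      chambers_per_delay = rows_per_delay * layout$n_cols,
      n_chambers_used = nrow(chambers),
      exposures_per_chamber = if (scheme == "dual") 2L else 1L,
      rows_consumed = rows_needed,
      rows_remaining = layout$n_rows - rows_needed,
      layout = layout
    ),
    class = "exposure_plan"
  )
}

#' @export
print.exposure_plan <- function(x, ...) {
  cat(sprintf(
    "<exposure_plan> %s-probing, %d delays x %d rows/delay: %d chambers/delay, %d used, %d rows left\n",
    x$scheme, length(x$delays), x$rows_per_delay,
    x$chambers_per_delay, x$n_chambers_used, x$rows_remaining
  ))
  invisible(x)
}

#' @rdname allocate_chambers
#' @param x An `exposure_plan`.
#' @param ... Unused.
#' @export
tidy.exposure_plan <- function(x, ...) x$chambers
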