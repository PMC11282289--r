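# Shared fixture builders; everything is generated in code at test time.

# Small chip for fast dataset tests: 6 rows x 8 columns.
tiny_layout <- function() chip_layout(n_rows = 6L, n_cols = 8L)

# Three-delay plan on the tiny chip.
tiny_plan <- function(scheme = "dual", delays = c(1e-4, 1e-3, 1e-2), rows_per_delay = 2L) {
  allocate_chambers(tiny_layout(), delays, rows_per_delay, scheme = scheme)
}

# Coarse q grid that still covers both analysis and normalisation windows.
tiny_q <- function(n = 120L) seq(0.01, 1.8, length.out = n)

tiny_basis <- function(q = tiny_q()) default_dissociation_basis(q)

tiny_model <- function() kinetic_model(tau = c(1.1e-3, 13.4e-3))

tiny_dataset <- function(noise = noise_model(0, seed = 1), plan = tiny_plan(),
                         basis = tiny_basis(), model = tiny_model()) {
  simulate_dataset(tiny_layout(), plan, basis, model, noise)
}

# Small chip carrying the full 10-delay half-decade series (one row, i.e.
# 4 chambers, per delay) on the full-resolution q grid.
ten_delay_dataset <- function(noise = noise_model(0, seed = 1)) {
  layout <- chip_layout(n_rows = 10L, n_cols = 4L)
  plan <- allocate_chambers(layout, delay_grid("half-decade"), 1L)
  simulate_dataset(layout, plan, default_dissociation_basis(), tiny_model(), noise)
}

# Independent brute-force azimuthal binning oracle: per-pixel double loop.
oracle_azimuthal <- function(image, geometry, edges) {
  ny <- nrow(image); nx <- ncol(image)
  nb <- length(edges) - 1L
  vals <- vector("list", nb)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      v <- image[i, j]
      if (is.na(v)) next
      r <- geometry$pixel_size_mm * sqrt((i - geometry$beam_center[2])^2 +
                                           (j - geometry$beam_center[1])^2)
      qq <- (4 * pi / geometry$wavelength_A) * sin(atan(r / geometry$distance_mm) / 2)
      for (b in seq_len(nb)) {
        if (qq >= edges[b] && qq < edges[b + 1L]) {
          vals[[b]] <- c(vals[[b]], v)
          break
        }
      }
    }
  }
  keep <- which(lengths(vals) > 0L)
  list(
    q = ((edges[-length(edges)] + edges[-1L]) / 2)[keep],
    intensity = vapply(vals[keep], mean, numeric(1)),
    sigma = vapply(vals[keep], function(v) {
      if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
    }, numeric(1)),
    count = lengths(vals)[keep]
  )
}
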