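test_that("Hampel despiking replaces spikes with the rolling median and nothing else", {
  q <- seq(0.01, 1.8, length.out = 150)
  smooth <- 100 * exp(-q^2 * 12^2 / 3) + 5
  clean <- scattering_curve(q, smooth)
  out <- hampel_despike(clean, window = 5, n_sigma = 3)
  expect_equal(out$intensity, smooth)
  expect_length(attr(out, "meta")$replaced_points, 0)

  spiked <- smooth
  spiked[70] <- 10 * median(smooth[65:75])
  cv <- scattering_curve(q, spiked)
  out <- hampel_despike(cv, window = 5, n_sigma = 3)
  # brute-force oracle: rolling median / MAD with truncated edges
  n <- length(spiked)
  for (i in seq_len(n)) {
    w <- spiked[max(1, i - 5):min(n, i + 5)]
    m <- median(w)
    s <- 1.4826 * median(abs(w - m))
    want <- if (abs(spiked[i] - m) > 3 * s) m else spiked[i]
    expect_identical(out$intensity[i], want)
  }
  expect_equal(attr(out, "meta")$replaced_points, 70L)

  const <- rep(4, 60); const[20] <- 50
  fixed <- hampel_despike(scattering_curve(seq_len(60) / 10, const), 5, 3)
  expect_equal(fixed$intensity, rep(4, 60))
  expect_error(hampel_despike(scattering_curve(1:5, 1:5), window = 5),
               class = "sxl_invalid_parameter")
})

test_that("window normalisation is scale-invariant, idempotent and unit-integral", {
  q <- tiny_q()
  cv <- scattering_curve(q, 50 * exp(-q) + 2, sigma = 0.1)
  n1 <- normalize_curve(cv)
  cv_scaled <- scattering_curve(q, cv$intensity * 37.5, sigma = cv$sigma * 37.5)
  expect_equal(normalize_curve(cv_scaled)$intensity, n1$intensity, tolerance = 1e-12)
  expect_equal(normalize_curve(n1)$intensity, n1$intensity, tolerance = 1e-12)
  inside <- q > 1.4 & q < 1.6
  w <- sxlkit:::trapz_weights(q) * inside
  expect_equal(sum(w * n1$intensity), 1, tolerance = 1e-12)
  # sigma scales with the same constant
  expect_equal(n1$sigma, cv$sigma / attr(n1, "meta")$norm_constant)
  short <- scattering_curve(seq(0.01, 1.0, length.out = 50), rep(1, 50))
  err <- expect_error(normalize_curve(short), class = "sxl_qrange_error")
  expect_match(conditionMessage(err), "1\\.0|\\b1\\b")
})

test_that("pairing subtracts normalised on/off partners and reports orphans", {
  ds <- tiny_dataset()
  dss <- pair_and_subtract(ds)
  expect_equal(nrow(dss$pairs), tiny_layout()$n_cols * 2 * 3)

  # on == off gives an identically zero difference
  q <- tiny_q()
  off <- scattering_curve(q, 10 * exp(-q), chamber = c(1, 1), laser_state = "off", delay = 1e-3)
  on <- scattering_curve(q, 10 * exp(-q), chamber = c(1, 1), laser_state = "on", delay = 1e-3)
  z <- pair_and_subtract(list(off, on), scheme = "dual")
  expect_equal(max(abs(z$delta)), 0)

  # noise-free synthetic difference equals the truth stored in the sidecar
  truth <- ds$truth
  expected <- truth$sads_norm %*% t(truth$populations)
  for (k in seq_len(nrow(dss$pairs))) {
    expect_equal(dss$delta[, k], expected[, dss$pairs$delay_index[k]], tolerance = 1e-9)
  }

  # a chamber missing its second exposure is named in the pairing error
  broken <- list(off, on, scattering_curve(q, 10 * exp(-q), chamber = c(2, 5),
                                           laser_state = "on", delay = 1e-3))
  err <- expect_error(pair_and_subtract(broken, scheme = "dual"), class = "sxl_pairing_error")
  expect_match(conditionMessage(err), "\\(2, 5\\)")
})

test_that("pairing commutes with scalar scaling of the raw intensities", {
  ds <- tiny_dataset(noise_model(0.02, seed = 3))
  d1 <- pair_and_subtract(ds)
  ds$intensity <- ds$intensity * 123.4
  d2 <- pair_and_subtract(ds)
  expect_equal(d2$delta, d1$delta, tolerance = 1e-12)
})

test_that("averaging keeps consistent curves, rejects corrupted ones, scales sigma 1/sqrt(n)", {
  q <- tiny_q(60)
  base <- 0.1 * exp(-q * 2) - 0.05
  mk <- function(y, col) {
    off <- scattering_curve(q, 10 * exp(-q) + 1, sigma = 0.01,
                            chamber = c(1, col), laser_state = "off", delay = 1e-3)
    on <- scattering_curve(q, (10 * exp(-q) + 1) * (1 + y), sigma = 0.01,
                           chamber = c(1, col), laser_state = "on", delay = 1e-3)
    list(off, on)
  }
  # 40 consistent pairs with tiny perturbations, 1 corrupted at 10x amplitude
  set.seed(5)
  curves <- list()
  for (cc in 1:39) curves <- c(curves, mk(base * (1 + rnorm(1, 0, 0.01)), cc))
  curves <- c(curves, mk(base * 10, 40))
  dm <- average_by_delay(pair_and_subtract(curves, scheme = "dual"), reject_n_sigma = 3)
  expect_equal(dm$n_rejected, 1L)
  expect_equal(dm$n_kept, 39L)

  # N identical curves average to themselves with sigma / sqrt(N)
  same <- unlist(lapply(1:8, function(cc) mk(base, cc)), recursive = FALSE)
  dss <- pair_and_subtract(same, scheme = "dual")
  dm2 <- average_by_delay(dss)
  expect_equal(dm2$delta[, 1], dss$delta[, 1])
  expect_equal(dm2$sigma[, 1], dss$sigma[, 1] / sqrt(8))

  # two mutually inconsistent noise-free curves both sit far from their
  # median: everything is rejected and the delay is reported degenerate
  two <- c(mk(base, 1), mk(-base * 5, 2))
  expect_error(average_by_delay(pair_and_subtract(two, scheme = "dual"),
                                reject_n_sigma = 0.5),
               class = "sxl_degenerate_delay")
})

test_that("variance of the averaged difference curve scales as 1/N", {
  # Monte-Carlo: with per-point noise sigma, the empirical variance of the
  # averaged DS over repeated simulations must drop as 1/N.
  q <- tiny_q(40)
  layout <- chip_layout(n_rows = 2L, n_cols = 16L)
  basis <- default_dissociation_basis(q)
  model <- tiny_model()
  one_avg <- function(seed, n_cols_used) {
    plan <- allocate_chambers(chip_layout(n_rows = 1L, n_cols = n_cols_used), 1e-3, 1L)
    ds <- simulate_dataset(chip_layout(n_rows = 1L, n_cols = n_cols_used), plan,
                           basis, model, noise_model(0.05, seed = seed))
    average_by_delay(pair_and_subtract(ds))$delta[5, 1]
  }
  v4 <- var(vapply(1:60, one_avg, numeric(1), n_cols_used = 4L))
  v16 <- var(vapply(61:120, one_avg, numeric(1), n_cols_used = 16L))
  expect_equal(v4 / v16, 4, tolerance = 0.6)
})

test_that("Guinier fits recover Rg exactly and flag non-Guinier curves", {
  q <- seq(0.005, 0.2, length.out = 80)
  exact <- scattering_curve(q, 100 * exp(-q^2 * 20^2 / 3))
  g <- guinier_fit(exact)
  expect_equal(g$Rg, 20, tolerance = 1e-10)
  expect_equal(g$I0, 100, tolerance = 1e-8)

  # homogeneous sphere: Rg = R sqrt(3/5)
  qs <- seq(0.002, 0.3, length.out = 300)
  R <- 30
  sph <- scattering_curve(qs, 50 * sphere_form_factor(qs, R))
  gs <- guinier_fit(sph, qRg_max = 1.0)
  expect_equal(gs$Rg, R * sqrt(3 / 5), tolerance = 0.01)

  rising <- scattering_curve(q, 1 + q^2)
  expect_error(guinier_fit(rising), class = "sxl_non_guinier_error")
})
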