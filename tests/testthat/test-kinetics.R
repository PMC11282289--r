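test_that("one-step chain follows the closed-form Bateman solution", {
  m <- kinetic_model(rates = 1000, phi = 0.8)
  t <- c(0, 1e-4, 1e-3, 1e-2)
  P <- bateman_populations(m, t)
  expect_equal(P$I1, 0.8 * exp(-1000 * t))
  expect_equal(P$P, 0.8 * (1 - exp(-1000 * t)))
})

test_that("populations are non-negative and conserve the excited fraction", {
  delays <- delay_grid("half-decade")
  for (rates in list(c(900, 75), c(5000, 900, 75), 123)) {
    m <- kinetic_model(rates = rates, phi = 0.7)
    P <- as.matrix(bateman_populations(m, delays)[, -1])
    expect_true(all(P >= -1e-14))
    expect_equal(unname(rowSums(P)), rep(0.7, length(delays)), tolerance = 1e-12)
  }
  # with ground-state recovery the total decays below phi
  mr <- kinetic_model(rates = c(900, 75), recovery_rate = 20)
  Pr <- as.matrix(bateman_populations(mr, delays)[, -1])
  expect_true(all(rowSums(Pr) <= 1 + 1e-12))
  expect_lt(sum(Pr[length(delays), ]), 1)
})

test_that("equal-rate (confluent) chains match a high-accuracy ODE oracle", {
  skip_if_not_installed("deSolve")
  delays <- c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 5e-2)
  oracle <- function(rates, recovery, times) {
    n <- length(rates) + 1L
    lam <- c(rates, if (is.null(recovery)) 0 else recovery)
    rhs <- function(t, y, parms) {
      dy <- -lam * y
      dy[-1] <- dy[-1] + rates * y[-n]
      list(dy)
    }
    out <- deSolve::ode(c(1, rep(0, n - 1L)), c(0, times), rhs, NULL,
                        method = "lsoda", rtol = 1e-12, atol = 1e-14)
    unname(out[-1, -1, drop = FALSE])
  }
  # exactly equal rates: confluent limit
  m_eq <- kinetic_model(rates = c(500, 500))
  got <- as.matrix(bateman_populations(m_eq, delays)[, -1])
  expect_equal(unname(got), oracle(c(500, 500), NULL, delays), tolerance = 1e-8)
  # near-equal rates route through the same confluent-safe path
  m_near <- kinetic_model(rates = c(500, 500 * (1 + 1e-12)))
  got_near <- as.matrix(bateman_populations(m_near, delays)[, -1])
  expect_equal(unname(got_near), oracle(c(500, 500), NULL, delays), tolerance = 1e-8)
  # well-separated rates: analytic Bateman sums against the oracle
  m_far <- kinetic_model(rates = c(909.09, 74.63))
  got_far <- as.matrix(bateman_populations(m_far, delays)[, -1])
  expect_equal(unname(got_far), oracle(c(909.09, 74.63), NULL, delays), tolerance = 1e-8)
  expect_error(kinetic_model(rates = c(100, -5)), class = "sxl_invalid_parameter")
})

test_that("SVD of the windowed matrix reconstructs, ranks and signs correctly", {
  q <- tiny_q()
  delays <- delay_grid("half-decade")
  basis <- default_dissociation_basis(q)
  P <- as.matrix(bateman_populations(tiny_model(), delays)[, -1])
  dm <- difference_matrix(q, delays, basis$sads[, c(1, 2)] %*% t(P[, c(1, 2)]))
  sv <- svd_analysis(dm)
  # rank-2 input: exactly 2 singular values above 1e-10 * s1
  expect_equal(sum(sv$d > 1e-10 * sv$d[1]), 2L)
  # reconstruction identity on the window
  rec <- sv$u %*% diag(sv$d) %*% t(sv$v)
  expect_lt(norm(rec - sv$windowed$delta, "F") / norm(sv$windowed$delta, "F"), 1e-10)
  # sign convention: largest-magnitude LSV element positive
  for (k in seq_along(sv$d)) expect_gt(sv$u[which.max(abs(sv$u[, k])), k], 0)
  expect_error(svd_analysis(dm, q_window = c(5, 6)), class = "sxl_window_error")
})

test_that("singular values agree with an independent Gram-matrix eigensolve", {
  set.seed(2)
  A <- matrix(rnorm(30), 6, 5)
  dm <- difference_matrix(seq(0.1, 0.6, by = 0.1), c(1e-4, 1e-3, 1e-2, 1e-1, 1), A)
  sv <- svd_analysis(dm, q_window = NULL)
  ev <- eigen(t(A) %*% A, symmetric = TRUE)$values
  expect_equal(sv$d, sqrt(rev(sort(ev))), tolerance = 1e-10)
})

test_that("component selection counts real species and ignores pure noise", {
  # noise-free 3-species sequential data -> exactly 3 significant
  ds <- ten_delay_dataset()
  dm <- reduce_dataset(ds)
  sel <- select_significant(svd_analysis(dm))
  expect_equal(sel$n_significant, 3L)

  # s = [10, ~0]: one significant component
  q <- seq(0.05, 0.95, length.out = 40)
  smooth <- exp(-q * 3)
  prof <- exp(-delay_grid("half-decade") / 1e-3)
  dm1 <- difference_matrix(q, delay_grid("half-decade"), outer(smooth, prof))
  sel1 <- select_significant(svd_analysis(dm1))
  expect_equal(sel1$n_significant, 1L)

  # pure noise: 0 significant components in at least 95 of 100 seeds
  zeros <- 0L
  for (s in 1:100) {
    set.seed(s)
    noise <- matrix(rnorm(40 * 10), 40, 10)
    dmn <- difference_matrix(q, delay_grid("half-decade"), noise)
    if (select_significant(svd_analysis(dmn))$n_significant == 0L) zeros <- zeros + 1L
  }
  expect_gte(zeros, 95L)
})

test_that("RSV exponential fits recover time constants and flag degeneracy", {
  delays <- delay_grid("half-decade")
  v <- 0.5 * exp(-delays / 1e-3) - 0.1
  fit <- fit_rsv_exponentials(delays, v, n_exp = 1)
  expect_equal(fit$tau, 1e-3, tolerance = 1e-6)
  expect_false(fit$ill_conditioned)

  v2 <- -0.7 * exp(-delays / 1.1e-3) - 0.3 * exp(-delays / 13.4e-3) + 0.05
  fit2 <- fit_rsv_exponentials(delays, v2, n_exp = 2)
  expect_equal(fit2$tau, c(1.1e-3, 13.4e-3), tolerance = 1e-6)
  expect_true(all(is.finite(fit2$tau_se)))
  expect_equal(tidy(fit2)$estimate[1:2], fit2$tau)

  flat <- fit_rsv_exponentials(delays, rep(0.2, length(delays)), n_exp = 1)
  expect_lt(abs(flat$amplitudes), 1e-6)
  expect_true(flat$ill_conditioned)
})

test_that("KCA recovers SADSs exactly on noise-free data and reports residuals", {
  ds <- ten_delay_dataset()
  dm <- reduce_dataset(ds, q_window = c(0.03, 1.0))
  kca <- kca_extract_sads(dm, tiny_model())
  truth <- ds$truth$sads_norm[ds$q >= 0.03 & ds$q <= 1.0, ]
  for (j in 1:3) {
    rel <- sqrt(mean((kca$sads[, j] - truth[, j])^2)) / sqrt(mean(truth[, j]^2))
    expect_lt(rel, 1e-10)
  }
  # zero residual in units of the data scale (arbitrary intensity units)
  expect_lt(kca$residual / sqrt(mean(dm$delta^2)), 1e-12)
  expect_equal(kca$theoretical, dm$delta, tolerance = 1e-10)

  # indistinguishable species on the probed grid raise identifiability errors
  late <- difference_matrix(dm$q, c(1, 2, 3), dm$delta[, 1:3])
  err <- expect_error(kca_extract_sads(late, kinetic_model(rates = c(1e5, 2e5))),
                      class = "sxl_identifiability_error")
  expect_match(conditionMessage(err), "I1|I2|P")
})

test_that("KCA at 1% noise recovers SADSs with r > 0.99 per species", {
  plan <- allocate_chambers(chip_layout(), delay_grid("half-decade"), 3L)
  ds <- simulate_dataset(chip_layout(), plan, default_dissociation_basis(tiny_q()),
                         tiny_model(), noise_model(0.01, seed = 31))
  dm <- reduce_dataset(ds, q_window = c(0.03, 1.0))
  kca <- kca_extract_sads(dm, tiny_model())
  truth <- ds$truth$sads_norm[ds$q >= 0.03 & ds$q <= 1.0, ]
  for (j in 1:3) expect_gt(cor(kca$sads[, j], truth[, j]), 0.99)
})

test_that("rate refinement never worsens the residual and recovers truth from 2x start", {
  ds <- ten_delay_dataset()
  dm <- reduce_dataset(ds, q_window = c(0.03, 1.0))
  truth_rates <- 1 / tiny_model()$tau

  at_truth <- refine_rates(dm, tiny_model())
  expect_lte(at_truth$residual, at_truth$residual0 + 1e-15)
  expect_equal(at_truth$model$rates, truth_rates, tolerance = 1e-4)

  off <- kinetic_model(rates = 2 * truth_rates)
  ref <- refine_rates(dm, off)
  expect_equal(ref$model$rates, truth_rates, tolerance = 1e-3)
  expect_lte(ref$residual, ref$residual0)
})

test_that("windowing changes nothing for data that vanish outside the window", {
  q <- tiny_q()
  delays <- delay_grid("half-decade")
  basis <- default_dissociation_basis(q)
  P <- as.matrix(bateman_populations(tiny_model(), delays)[, -1])
  M <- basis$sads %*% t(P)
  M[q < 0.03 | q > 1.0, ] <- 0
  dm <- difference_matrix(q, delays, M)
  svd_full <- svd_analysis(dm, q_window = NULL)
  svd_win <- svd_analysis(dm, q_window = c(0.03, 1.0))
  expect_equal(svd_win$d[1:3], svd_full$d[1:3], tolerance = 1e-12)
})
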