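test_that("sphere form factor has unit forward limit and stays in [0, 1]", {
  q <- seq(0, 2, by = 0.002)
  P <- sphere_form_factor(q, radius = 30)
  expect_equal(P[1], 1)
  expect_true(all(P >= 0 & P <= 1))
  # series and closed-form branches agree at the switchover (qR ~ 1e-2)
  x <- c(0.0099, 0.0101)
  closed <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  expect_equal(sphere_form_factor(x / 30, 30), closed, tolerance = 1e-8)
  expect_error(sphere_form_factor(q, radius = -1), class = "sxl_invalid_parameter")
  expect_error(sphere_form_factor(c(-0.1, 0.1), radius = 1), class = "sxl_invalid_parameter")
})

test_that("first zero of the sphere amplitude sits at qR ~ 4.493, found by bisection", {
  amp <- function(x) 3 * (sin(x) - x * cos(x)) / x^3
  lo <- 4; hi <- 5
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(amp(mid)) == sign(amp(lo))) lo <- mid else hi <- mid
  }
  x_root <- (lo + hi) / 2
  expect_equal(x_root, 4.493409, tolerance = 1e-6)
  R <- 30
  expect_lt(sphere_form_factor(x_root / R, R), 1e-20)
})

test_that("form factor at qR = 2 matches independent closed-form evaluation", {
  # direct evaluation, independent of the package's vectorised/branched code
  expected <- (3 * (sin(2) - 2 * cos(2)) / 8)^2
  expect_equal(sphere_form_factor(2 / 25, 25), expected, tolerance = 1e-14)
})

test_that("dimer intensity carries the two-body interference term", {
  R <- 25; d <- 55
  mono <- scattering_model("monomer-sphere", radius = R)
  dim2 <- scattering_model("dimer-of-spheres", radius = R, center_distance = d)
  # q -> 0: interference term -> 1, so I_dimer = 4 I_monomer
  expect_equal(assembly_intensity(dim2, 0), 4 * assembly_intensity(mono, 0))
  # qd >> 1: interference term -> 0, I_dimer -> 2 I_monomer
  q_hi <- seq(2.0, 2.5, by = 0.01)
  expect_equal(assembly_intensity(dim2, q_hi), 2 * assembly_intensity(mono, q_hi),
               tolerance = 2e-2)
  # brute-force evaluation of the full formula at one point
  q0 <- 0.05
  Pq <- (3 * (sin(q0 * R) - q0 * R * cos(q0 * R)) / (q0 * R)^3)^2
  expect_equal(assembly_intensity(dim2, q0), 2 * Pq * (1 + sin(q0 * d) / (q0 * d)),
               tolerance = 1e-14)
  expect_error(scattering_model("dimer-of-spheres", radius = 25, center_distance = 40),
               class = "sxl_invalid_parameter")
})

test_that("SADS basis carries the dissociation/association sign laws", {
  q <- tiny_q()
  # intermediate identical to ground -> SADS identically zero (raw gauge)
  g <- scattering_model("dimer-of-spheres", radius = 25)
  same <- make_sads_basis(g, list(g), q, gauge_window = NULL)
  expect_equal(max(abs(same$sads)), 0)

  # dimer -> two free monomers at q = 0 exactly: SADS(0) = 2A - 4A < 0
  q0 <- c(0, q)
  two_free <- scattering_model("monomer-sphere", radius = 25, contrast_volume = sqrt(2))
  dis <- make_sads_basis(g, list(two_free), q0, gauge_window = NULL)
  expect_equal(dis$sads[1, 1], 2 - 4)

  # monomer -> dimer association: SADS(0) > 0
  m <- scattering_model("monomer-sphere", radius = 22)
  dimer <- scattering_model("dimer-of-spheres", radius = 22)
  assoc <- make_sads_basis(m, list(dimer), q0, gauge_window = NULL)
  expect_equal(assoc$sads[1, 1], 4 - 1)

  # the gauge projection zeroes each SADS's normalisation-window integral
  # while preserving the low-q sign
  gauged <- default_dissociation_basis(q)
  w <- diff(q)[1]
  inside <- q > 1.4 & q < 1.6
  for (j in seq_len(ncol(gauged$sads))) {
    expect_lt(abs(sum(gauged$sads[inside, j]) * w), 1e-10)
  }
  expect_lt(gauged$sads[1, 2], 0)

  expect_error(make_sads_basis(g, list(), q), class = "sxl_invalid_parameter")
  expect_error(make_sads_basis(g, list(two_free), rev(q)), class = "sxl_grid_error")
})
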