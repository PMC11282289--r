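test_that("identical seeds reproduce a dataset bit-exactly, different seeds do not", {
  a <- tiny_dataset(noise_model(0.05, chamber_jitter = 0.02, seed = 42))
  b <- tiny_dataset(noise_model(0.05, chamber_jitter = 0.02, seed = 42))
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$sigma, b$sigma)
  c <- tiny_dataset(noise_model(0.05, chamber_jitter = 0.02, seed = 43))
  expect_false(identical(a$intensity, c$intensity))
})

test_that("noise-free laser-on minus laser-off reproduces sum_i SADS_i P_i exactly", {
  ds <- tiny_dataset()
  truth <- ds$truth
  expected <- truth$sads_raw %*% t(truth$populations)   # q x delays
  ex <- ds$exposures
  for (pid in unique(ex$pair_id)) {
    off <- which(ex$pair_id == pid & ex$laser_state == "off")
    on <- which(ex$pair_id == pid & ex$laser_state == "on")
    di <- ex$delay_index[on]
    expect_equal(ds$intensity[, on] - ds$intensity[, off], expected[, di],
                 tolerance = 1e-12)
  }
})

test_that("dual probing gives two exposures per chamber in off-then-on order", {
  ds <- tiny_dataset()
  ex <- ds$exposures
  counts <- table(paste(ex$row, ex$col))
  expect_true(all(counts == 2L))
  per <- split(ex, ex$pair_id)
  for (p in per) expect_equal(p$laser_state[order(p$exposure)], c("off", "on"))

  ds1 <- tiny_dataset(plan = tiny_plan(scheme = "single"))
  expect_true(all(table(paste(ds1$exposures$row, ds1$exposures$col)) == 1L))
})

test_that("plans that exceed chip capacity fail before generating data", {
  # 4 delays x 2 rows/delay needs 8 rows; the tiny chip has 6
  big_plan <- allocate_chambers(chip_layout(), c(1e-5, 1e-4, 1e-3, 1e-2), 2L)
  err <- expect_error(
    simulate_dataset(tiny_layout(), big_plan, tiny_basis(), tiny_model(), noise_model(0)),
    class = "sxl_capacity_error"
  )
  expect_match(conditionMessage(err), "short by 2")
})

test_that("stored sigma follows the heteroscedastic noise law", {
  nm <- noise_model(relative_sigma = 0.03, floor = 0.01, seed = 7)
  ds <- tiny_dataset(nm)
  ex <- ds$exposures
  off1 <- which(ex$laser_state == "off")[1]
  ideal <- ds$truth$ground * ex$scale[off1]
  expect_equal(ds$sigma[, off1], 0.03 * abs(ideal) + 0.01, tolerance = 1e-12)
})

test_that("capillary degradation follows the geometric decay and aggregation laws", {
  basis <- tiny_basis()
  # f = 0: all repetitions identical
  still <- simulate_capillary_series(basis, 5, damage_fraction_per_shot = 0)
  expect_equal(still$ds[, 5], still$ds[, 1])
  expect_equal(still$static[, 5], still$static[, 1])

  # f = 0.2: DS amplitude at r = 10 is 0.8^10 of r = 0
  s <- simulate_capillary_series(basis, 11, damage_fraction_per_shot = 0.2,
                                 aggregation_scale = 0.5)
  expect_equal(s$summary$ds_amplitude[11] / s$summary$ds_amplitude[1], 0.8^10,
               tolerance = 1e-12)
  expect_equal(s$ds[, 11], s$ds[, 1] * 0.8^10, tolerance = 1e-12)

  # aggregation raises the Guinier-region static intensity monotonically
  expect_true(all(diff(s$summary$guinier_intensity) > 0))
  expect_true(all(diff(s$static[1, ]) > 0))

  expect_error(simulate_capillary_series(basis, 0), class = "sxl_invalid_parameter")
  expect_error(simulate_capillary_series(basis, 3, damage_fraction_per_shot = 1.5),
               class = "sxl_invalid_parameter")
})
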