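test_that("chip layout arithmetic and default sample load are consistent", {
  chip <- chip_layout()
  expect_equal(chip$n_chambers, 1200L)
  expect_equal(chip$per_chamber_mass_ng,
               chip$chamber_volume_nl * 1e-9 * chip$sample_concentration_M *
                 chip$molecular_weight * 1e9)
  expect_equal(chip$total_mass_ug, chip$per_chamber_mass_ng * 1200 / 1e3)
})

test_that("chamber allocation is zigzag, non-overlapping and capacity-checked", {
  chip <- chip_layout()
  plan <- allocate_chambers(chip, delay_grid("half-decade"), 3L)
  expect_equal(plan$chambers_per_delay, 120L)
  expect_equal(plan$rows_consumed, 30L)
  expect_equal(plan$rows_remaining, 0L)
  ch <- tidy(plan)
  # no chamber reused; union covers delays x rows x cols exactly
  expect_equal(anyDuplicated(ch$chamber_id), 0L)
  expect_equal(nrow(ch), 10L * 3L * 40L)
  # zigzag: odd rows ascend, even rows descend
  expect_equal(ch$col[ch$row == 1], 1:40)
  expect_equal(ch$col[ch$row == 2], 40:1)

  one <- allocate_chambers(chip, 1e-3, 1L)
  expect_equal(one$chambers_per_delay, 40L)
  expect_equal(one$rows_remaining, 29L)

  expect_error(allocate_chambers(chip, 10^seq(-5, 0, by = 0.5), 3L),
               class = "sxl_capacity_error")
  expect_error(allocate_chambers(chip, 10^seq(-5, 0, by = 0.5), 3L),
               regexp = "short by")
})

test_that("single-probing plans pair adjacent columns within a row", {
  plan <- tiny_plan(scheme = "single")
  ch <- tidy(plan)
  expect_true(all(table(ch$pair_id) == 2L))
  by_pair <- split(ch, ch$pair_id)
  for (p in by_pair) {
    expect_equal(abs(diff(p$col)), 1L)
    expect_equal(length(unique(p$row)), 1L)
    expect_setequal(p$role, c("off", "on"))
  }
})

test_that("budget quantities are exact with report-only rounding", {
  expect_equal(mass_per_ds(0, 5)$value, 0)
  b <- sample_budget(100, 3)
  expect_equal(b$per_ds_mass_ug, 100 / 3)          # full precision retained
  expect_equal(b$per_ds_mass_ug_report, 33)        # 2 significant figures
  expect_equal(efficiency_ratio(b, b)$ratio, 1)
  expect_error(sample_budget(10, 0), class = "sxl_invalid_parameter")
  expect_equal(photon_budget(5, 0), 0)
  # report rounding is half-away-from-zero at 2 significant figures
  expect_equal(sample_budget(2.5, 1)$per_ds_mass_ug_report, 2.5)
  expect_equal(sample_budget(125, 1)$per_ds_mass_ug_report, 130)
})

test_that("budget_table combines chip, plan and pulse-train arithmetic", {
  chip <- chip_layout()
  plan <- allocate_chambers(chip, delay_grid("half-decade"), 3L)
  tab <- budget_table(chip, plan, photons_per_pulse = 3e9, n_pulses = 11)
  expect_equal(tab$value[tab$quantity == "chambers_per_delay"], 120)
  expect_equal(tab$value[tab$quantity == "photons_per_train"], 3.3e10)
  expect_equal(tab$value[tab$quantity == "mass_used_ug"],
               chip$per_chamber_mass_ng * 1200 / 1e3)
})
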