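test_that("transition classification follows the category definitions", {
  expect_identical(classify_transition("primary_old_growth", 2005L, FALSE),
                   "FL_OL")
  expect_identical(classify_transition("old_secondary", NA, FALSE), "FL_FL")
  expect_identical(classify_transition("nonforest", NA, TRUE), "OL_FL")
  expect_identical(classify_transition("nonforest", NA, FALSE), NA_character_)
  # cropland convention for tree crops
  expect_identical(classify_transition("tree_crop", NA, FALSE, TRUE), "CL_CL")
  expect_identical(classify_transition("tree_crop", NA, TRUE, TRUE), "OL_CL")
  expect_identical(classify_transition("tree_crop", NA, FALSE, FALSE), "FL_FL")
  expect_identical(classify_transition("tree_crop", 2010L, FALSE, FALSE),
                   "FL_OL")
  expect_error(classify_transition("nonforest", 2010L, FALSE),
               "loss recorded on nonforest")
})

test_that("committed emissions expand pools and convert to CO2", {
  f <- simple_factors(rs = 0.25, dw = 0, lit = 0)
  expect_equal(committed_emission(100, f, 1), 125 * 44 / 12)
  expect_equal(committed_emission(0, f, 1), 0)
  f2 <- simple_factors(rs = 0.25, dw = 0.10, lit = 0.04)
  expect_equal(committed_emission(100, f2, 0.09), 0.09 * 139 * 44 / 12)
  # soil term only when requested
  f3 <- simple_factors(rs = 0.25, dw = 0, lit = 0, soil = 20)
  expect_equal(committed_emission(100, f3, 1, include_soil = TRUE),
               (125 + 20) * 44 / 12)
  expect_equal(committed_emission(100, f3, 1, include_soil = FALSE),
               125 * 44 / 12)
  expect_error(committed_emission(-1, f, 1), "negative AGC")
  expect_error(committed_emission(10, f, 0), "area")
})

test_that("removal flux accrues up to the loss year and never turns positive", {
  f <- simple_factors()
  expect_equal(removal_flux("primary_old_growth", "*", NA, f, 1, c(2001, 2020)),
               -0.59 * 44 / 12)
  f0 <- factor_table(tibble::tibble(biome = "*", forest_type = "old_secondary",
                                    rf_central = 0))
  expect_equal(removal_flux("old_secondary", "*", NA, f0, 1, c(2001, 2020)), 0)
  f1 <- factor_table(tibble::tibble(biome = "*",
                                    forest_type = "primary_old_growth",
                                    rf_central = 1))
  # lost in year 11 of a 20-year period starting in year 1: 10 accrual years
  expect_equal(removal_flux("primary_old_growth", "*", 11L, f1, 1, c(1, 20)),
               -(10 / 20) * 44 / 12)
  expect_error(removal_flux("nonforest", "*", NA, f, 1, c(2001, 2020)),
               "no removal factor")
})

test_that("stratum resolution prefers exact biome rows over wildcards", {
  f <- factor_table(tibble::tibble(
    biome = c("*", "biome_2"),
    forest_type = c("primary_old_growth", "primary_old_growth"),
    rf_central = c(0.5, 0.9)))
  expect_equal(resolve_removal_factor(f, c("biome_1", "biome_2"),
                                      rep("primary_old_growth", 2)),
               c(0.5, 0.9))
})

test_that("unit conversions are stoichiometric", {
  expect_equal(convert_units(12, "c_to_co2"), 44)
  expect_equal(convert_units(100, "biomass_to_c"), 47)
  expect_equal(convert_units(0, "c_to_co2"), 0)
})

test_that("vectorized engine matches the per-cell loop oracle", {
  f <- tropical_default_factors(peat_decomposition = 19, peat_fire = 55,
                                flfl_burn_emission = 7, soil_emission = 30)
  for (seed in c(2, 9)) {
    st <- random_stack(seed)
    for (opt in list(gainloss_options(),
                     gainloss_options(include_soil = TRUE, include_peat = TRUE,
                                      treat_tree_crops_as_cropland = FALSE,
                                      removals_on_loss_cells = FALSE,
                                      gain_accrual_fraction = 1))) {
      led <- run_gain_loss(st, f, opt)
      expect_ledger_equal(led, oracle_ledger(st, f, opt))
    }
  }
})

test_that("single-cell ledgers equal the per-pixel operations directly", {
  f <- simple_factors(rs = 0.2, dw = 0.1, lit = 0.05)
  st <- grid_stack(
    matrix("primary_old_growth"), matrix(120), matrix(2011L), matrix(FALSE),
    matrix(TRUE), matrix(TRUE), matrix("primary_old_growth"), matrix(1L),
    matrix(FALSE), cell_area = 0.09, period = c(2001L, 2020L))
  led <- run_gain_loss(st, f)
  n <- 20
  em <- led$value[led$component == "emission_deforestation"]
  rm_ <- led$value[led$component == "removal"]
  expect_equal(em, committed_emission(120, f, 0.09) / n)
  expect_equal(rm_, removal_flux("primary_old_growth", "*", 2011L, f, 0.09,
                                 c(2001, 2020)))
  expect_identical(unique(led$category), "FL_OL")
})

test_that("sign discipline, scale equivariance and biome additivity hold", {
  f <- tropical_default_factors()
  st <- random_stack(4)
  led <- run_gain_loss(st, f)
  expect_true(all(led$value[led$component == "removal"] <= 0))
  expect_true(all(led$value[led$component != "removal"] >= 0))
  expect_equal(net_flux(led), gross_emissions(led) + gross_removals(led))

  st2 <- st; st2$cell_area <- 2 * st$cell_area
  led2 <- run_gain_loss(st2, f)
  expect_equal(led2$value, 2 * led$value)

  # merging regions preserves every booked total
  stc <- st; stc$biome <- matrix(1L, nrow(st$biome), ncol(st$biome))
  ledc <- run_gain_loss(stc, f)
  merged <- ledger_total(led, by = c("category", "forest_type", "component"))
  country <- ledger_total(ledc, by = c("category", "forest_type", "component"))
  expect_equal(dplyr::arrange(merged, category, forest_type, component),
               dplyr::arrange(country, category, forest_type, component))
})

test_that("degenerate landscapes produce degenerate ledgers", {
  f <- tropical_default_factors()
  h <- 6; w <- 6
  st <- grid_stack(matrix("nonforest", h, w), matrix(0, h, w),
                   matrix(NA_integer_, h, w), matrix(FALSE, h, w),
                   matrix(TRUE, h, w), matrix(FALSE, h, w),
                   matrix("nonforest", h, w), matrix(1L, h, w),
                   matrix(FALSE, h, w), cell_area = 1, period = c(2001L, 2020L))
  led <- run_gain_loss(st, f)
  expect_equal(nrow(led), 0L)
  expect_equal(net_flux(led), 0)

  # without loss events: no deforestation emissions, removals at full accrual
  st2 <- random_stack(6, p_loss = 0, p_gain = 0, with_burn = FALSE)
  led2 <- run_gain_loss(st2, f)
  expect_false("emission_deforestation" %in% led2$component)
  forest <- st2$forest_type_t0 != "nonforest"
  full <- sum(-st2$cell_area * 44 / 12 *
                resolve_removal_factor(f, paste0("biome_", st2$biome[forest]),
                                       st2$forest_type_t0[forest]))
  expect_equal(gross_removals(led2), full)
})

test_that("misaligned layers are rejected", {
  st <- random_stack(1)
  st$agc_t0 <- st$agc_t0[, -1]
  expect_error(validate_grid_stack(st), "mismatched dimensions")
})
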