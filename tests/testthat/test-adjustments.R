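test_that("the built-in ladder has the five named configurations", {
  specs <- builtin_specs()
  expect_setequal(names(specs),
                  c("no_adjustment", "adjustment_1", "adjustment_2a",
                    "adjustment_2b", "adjustment_2c"))
  expect_true(all(specs$no_adjustment$rules$include))
  # adjustment 1 drops primary removals only
  r1 <- specs$adjustment_1$rules
  excluded <- r1[!r1$include, ]
  expect_true(all(excluded$forest_type == "primary_old_growth"))
  expect_true(all(excluded$component_class == "removal"))
  expect_true(all(specs$adjustment_2c$extra_exclusions))
})

test_that("no_adjustment reproduces the unadjusted ledger", {
  st <- generate_landscape(landscape_config(32, seed = 21))
  f <- tropical_default_factors()
  base <- run_gain_loss(st, f)
  adj <- apply_adjustment(st, f, "no_adjustment")
  expect_equal(adj$value, base$value)
  expect_identical(adj$provenance[1], "no_adjustment")
  expect_equal(nrow(complement_ledger(adj)), 0L)
})

test_that("primary-forest removals are excluded but emissions kept country-wide", {
  st <- generate_landscape(landscape_config(32, seed = 22))
  f <- tropical_default_factors()
  base <- run_gain_loss(st, f)
  a1 <- apply_adjustment(st, f, "adjustment_1")
  expect_equal(gross_emissions(a1), gross_emissions(base))
  expect_false(any(a1$forest_type == "primary_old_growth" &
                     a1$component == "removal"))
  expect_gt(gross_removals(a1), gross_removals(base))  # smaller magnitude
})

test_that("2c zeroes secondary-remaining-forest, undisturbed-plantation and tree-crop removals", {
  st <- generate_landscape(landscape_config(32, seed = 23))
  f <- tropical_default_factors()
  a2c <- apply_adjustment(st, f, "adjustment_2c")
  bad <- a2c$component == "removal" &
    ((a2c$forest_type == "old_secondary" & a2c$category == "FL_FL") |
       (a2c$forest_type == "plantation_forest" & a2c$category == "FL_FL") |
       a2c$forest_type == "tree_crop" |
       a2c$category == "FL_OL")
  expect_false(any(bad))
  # disturbed plantations (FL_OL emissions) survive on managed land
  expect_true(any(a2c$forest_type == "plantation_forest" &
                    a2c$component == "emission_deforestation"))
})

test_that("removal magnitude is monotone along the ladder and complements are exact", {
  f <- tropical_default_factors()
  specs <- builtin_specs()
  for (seed in 31:35) {
    st <- generate_landscape(landscape_config(24, seed = seed,
                                              peat_fraction = 0.1))
    base <- run_gain_loss(st, f)
    led <- lapply(specs, function(s) apply_adjustment(st, f, s))
    r <- vapply(led, gross_removals, numeric(1))
    expect_lte(abs(r[["adjustment_2c"]]), abs(r[["adjustment_2b"]]) + 1e-12)
    expect_lte(abs(r[["adjustment_2b"]]), abs(r[["adjustment_2a"]]) + 1e-12)
    expect_lte(abs(r[["adjustment_2a"]]), abs(r[["no_adjustment"]]) + 1e-12)
    expect_lte(abs(r[["adjustment_1"]]), abs(r[["no_adjustment"]]) + 1e-12)
    for (nm in names(led)) {
      comp <- complement_ledger(led[[nm]])
      both <- dplyr::bind_rows(tibble::as_tibble(led[[nm]]),
                               tibble::as_tibble(comp)) |>
        dplyr::group_by(region, category, forest_type, component) |>
        dplyr::summarise(value = sum(value), .groups = "drop") |>
        dplyr::filter(abs(value) > 0) |>
        dplyr::arrange(region, category, forest_type, component)
      ref <- dplyr::arrange(tibble::as_tibble(base)[names(both)],
                            region, category, forest_type, component)
      expect_equal(both, ref, tolerance = 1e-12)
    }
  }
})

test_that("fully managed landscapes collapse 2a onto no_adjustment", {
  st <- generate_landscape(landscape_config(32, seed = 41,
                                            unmanaged_block_fraction = 0))
  f <- tropical_default_factors()
  base <- apply_adjustment(st, f, "no_adjustment")
  a2a <- apply_adjustment(st, f, "adjustment_2a")
  expect_equal(a2a$value, base$value)

  # with managed forest equal to the true forest extent, 2b differs from 2a
  # only by the forest-converted-to-other-land removal exclusion
  st$managed_forest <- matrix(st$forest_type_t0 != "nonforest" | st$gain_flag,
                              nrow(st$managed_forest))
  a2b <- apply_adjustment(st, f, "adjustment_2b")
  a2a <- apply_adjustment(st, f, "adjustment_2a")
  kept <- !(a2a$component == "removal" & a2a$category == "FL_OL")
  expect_equal(a2b$value, a2a$value[kept])
})

test_that("a missing required mask layer fails by name", {
  st <- generate_landscape(landscape_config(16, seed = 42))
  st$managed_forest <- NULL
  f <- tropical_default_factors()
  expect_error(apply_adjustment(st, f, "adjustment_2b"), "managed_forest")
  expect_error(apply_adjustment(st, f, "nonsense"), "unknown adjustment")
})

test_that("adjustment specs round-trip through YAML", {
  dir <- withr::local_tempdir()
  for (nm in c("adjustment_1", "adjustment_2c")) {
    spec <- builtin_specs()[[nm]]
    path <- file.path(dir, paste0(nm, ".yml"))
    write_adjustment_spec(spec, path)
    back <- read_adjustment_spec(path)
    expect_identical(back$name, spec$name)
    expect_identical(back$emission_mask, spec$emission_mask)
    expect_identical(back$removal_mask, spec$removal_mask)
    expect_equal(back$extra_exclusions[order(names(back$extra_exclusions))],
                 spec$extra_exclusions[order(names(spec$extra_exclusions))])
    a <- dplyr::arrange(spec$rules, category, forest_type, component_class)
    b <- dplyr::arrange(back$rules, category, forest_type, component_class)
    expect_equal(a$include, b$include)
  }
})
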