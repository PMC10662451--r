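test_that("modal factor picks the most frequent value, smallest on ties", {
  expect_equal(modal_factor(matrix(0.24, 5, 5), matrix(TRUE, 5, 5)), 0.24)
  layer <- c(rep(0.59, 60), rep(0.24, 40))
  expect_equal(modal_factor(layer, rep(TRUE, 100)), 0.59)
  tie <- c(rep(0.59, 50), rep(0.24, 50))
  expect_equal(modal_factor(tie, rep(TRUE, 100)), 0.24)
  expect_error(modal_factor(layer, rep(FALSE, 100)), "empty-stratum")
  # result is a member of the stratum's value set
  set.seed(1)
  v <- sample(c(0.2, 0.44, 0.95), 57, replace = TRUE)
  expect_true(modal_factor(v, rep(TRUE, 57)) %in% v)
})

test_that("percentage differences round half away from zero", {
  expect_equal(pct_difference(0.59, 0.48), 23)
  expect_equal(pct_difference(11.2, 12.5, 1), -10.4)
  expect_equal(pct_difference(2.8, 3.2), -13)  # -12.5 rounds away from zero
  expect_equal(pct_difference(5, 5), 0)
  expect_error(pct_difference(1, 0), "undefined-difference")
  # reciprocal identity before rounding
  for (pair in list(c(0.59, 0.48), c(11.2, 12.5), c(4.5, 0.7))) {
    p_ab <- 100 * (pair[1] - pair[2]) / pair[2]
    p_ba <- 100 * (pair[2] - pair[1]) / pair[1]
    expect_equal((1 + p_ab / 100) * (1 + p_ba / 100), 1)
  }
})

test_that("cross-tabulation counts, normalizes and flags empty rows", {
  m <- matrix(sample(forest_type_levels(), 400, replace = TRUE), 20, 20)
  ct <- cross_tabulate(m, m)
  expect_equal(diag(ct$percentages)[rowSums(ct$counts) > 0],
               rep(100, sum(rowSums(ct$counts) > 0)), ignore_attr = TRUE)
  rs <- rowSums(ct$percentages)
  expect_true(all(abs(rs[rowSums(ct$counts) > 0] - 100) < 1e-6))
  expect_equal(sum(ct$counts), 400)

  mask <- matrix(FALSE, 20, 20)
  ct0 <- cross_tabulate(m, m, mask)
  expect_true(all(ct0$counts == 0))
  expect_setequal(ct0$zero_rows, forest_type_levels())

  # configured relabeling is recovered within 3 standard errors
  set.seed(5)
  n <- 10000
  a <- rep("old_secondary", n)
  flip <- stats::runif(n) < 0.65
  b <- ifelse(flip, "primary_old_growth", "old_secondary")
  ct2 <- cross_tabulate(matrix(a, 100), matrix(b, 100))
  est <- ct2$percentages["old_secondary", "primary_old_growth"] / 100
  expect_lt(abs(est - 0.65), 3 * sqrt(0.65 * 0.35 / n))

  expect_error(cross_tabulate(m, m[, -1]), "misaligned")
})

test_that("mask overlap percentages use the second mask as denominator", {
  a <- matrix(c(rep(TRUE, 11), rep(FALSE, 89)), 10)
  b <- matrix(TRUE, 10, 10)
  expect_equal(overlap_percent(a, b), 11)
  expect_equal(overlap_percent(b, b), 100)
  expect_equal(overlap_percent(!b, b), 0)
  expect_error(overlap_percent(b, !b), "empty-denominator")
})

test_that("area tables report thousand hectares and tile-invariantly", {
  h <- 10; w <- 10
  st <- grid_stack(matrix("plantation_forest", h, w), matrix(50, h, w),
                   matrix(NA_integer_, h, w), matrix(FALSE, h, w),
                   matrix(TRUE, h, w), matrix(TRUE, h, w),
                   matrix("plantation_forest", h, w), matrix(1L, h, w),
                   matrix(FALSE, h, w), cell_area = 0.09,
                   period = c(2001L, 2020L))
  at <- area_table(st)
  expect_equal(at$area_kha, 100 * 0.09 / 1000)

  st2 <- generate_landscape(landscape_config(40, seed = 13))
  whole <- area_table(st2)
  halves <- lapply(list(1:20, 21:40), function(rows) {
    part <- st2
    for (nm in fluxgap:::.stack_layer_names(st2)) {
      part[[nm]] <- st2[[nm]][rows, , drop = FALSE]
    }
    area_table(part)
  })
  summed <- dplyr::bind_rows(halves) |>
    dplyr::group_by(region, type) |>
    dplyr::summarise(area_kha = sum(area_kha), .groups = "drop")
  expect_equal(dplyr::arrange(summed, region, type),
               dplyr::arrange(whole, region, type))
})

test_that("swamp:dry ratios summarise the packaged land-area tables", {
  areas <- ref_land_areas_seasia()
  ind <- function(ds) areas[areas$country == "indonesia" & areas$dataset == ds, ]
  swamp <- function(t) t$land_type[t$wetness == "swamp"]
  dry <- function(t) t$land_type[t$wetness == "dry"]
  expect_equal(swamp_dry_ratio(ind("nghgi"), swamp(ind("nghgi")),
                               dry(ind("nghgi"))), 0.15)
  expect_equal(swamp_dry_ratio(ind("eo"), swamp(ind("eo")), dry(ind("eo"))),
               0.13)
  eq <- tibble::tibble(land_type = c("s", "d"), area_kha = c(5, 5))
  expect_equal(swamp_dry_ratio(eq, "s", "d"), 1.00)
  z <- tibble::tibble(land_type = c("s", "d"), area_kha = c(5, 0))
  expect_error(swamp_dry_ratio(z, "s", "d"), "undefined-ratio")
  expect_error(swamp_dry_ratio(eq, "missing", "d"), "mapping error")
})

test_that("AGC summaries match closed-form lognormal quantiles", {
  const <- matrix(80, 5, 5)
  s <- agc_summary(const, matrix(TRUE, 5, 5))
  expect_equal(unname(s), rep(80, 4))

  set.seed(11)
  v <- stats::rlnorm(1e4, log(120), 0.4)
  s2 <- agc_summary(matrix(v, 100), matrix(TRUE, 100, 100))
  probs <- c(q1 = 0.25, median = 0.5, q3 = 0.75)
  for (nm in names(probs)) {
    th <- stats::qlnorm(probs[[nm]], log(120), 0.4)
    expect_lt(abs(s2[[nm]] - th) / th, 0.02)
  }
  expect_error(agc_summary(const, matrix(FALSE, 5, 5)), "empty-stratum")

  lo <- c(mean = 0.5, q1 = 0, median = 0.5, q3 = 1)
  hi <- c(mean = 2.5, q1 = 2, median = 2.5, q3 = 3)
  expect_false(iqr_overlap(lo, hi))
  expect_true(iqr_overlap(lo, c(mean = 1, q1 = 0.8, median = 1, q3 = 2)))
})

test_that("removals-by-type reports total the unrounded columns", {
  t4 <- ref_area_removals_brazil()
  tabs <- lapply(split(t4, t4$dataset), function(d) {
    tibble::tibble(forest_type = d$forest_type, area_kha = d$area_kha,
                   gross_removals = d$gross_removals_gt)
  })
  rep_ <- removals_by_type_report(tabs)
  tot <- rep_[rep_$forest_type == "Total", ]
  expect_equal(tot$eo_gross_removals, -0.77)
  expect_equal(tot$nghgi_gross_removals, -0.45)
  expect_equal(tot$eo_area_kha, 258463)
  expect_equal(tot$nghgi_area_kha, 258463)
  expect_equal(tot$seeg_area_kha, 258463)

  single <- list(x = tibble::tibble(forest_type = "plantation_forest",
                                    area_kha = 5, gross_removals = -0.1))
  r1 <- removals_by_type_report(single)
  expect_equal(r1$x_area_kha, c(5, 5))

  perm <- removals_by_type_report(tabs[c(3, 1, 2)])
  expect_setequal(names(perm), names(rep_))
  expect_equal(perm$eo_gross_removals, rep_$eo_gross_removals)
})
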