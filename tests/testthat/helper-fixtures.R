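# Shared fixtures: hand-set factor tables, random stacks built directly (not
# via the generator), and a naive per-cell loop oracle for the engine.

simple_factors <- function(rs = 0.25, dw = 0, lit = 0, soil = 0, ...) {
  factor_table(
    tibble::tibble(
      biome = "*",
      forest_type = c("primary_old_growth", "old_secondary", "young_secondary",
                      "plantation_forest", "tree_crop"),
      rf_central = c(0.59, 1.36, 4.5, 12.7, 3.0)),
    root_shoot_ratio = rs, deadwood_ratio = dw, litter_ratio = lit,
    soil_emission = soil, ...)
}

# i.i.d. random stack with all layer kinds populated; no spatial structure
# needed for engine equivalence checks
random_stack <- function(seed, h = 16, w = 16, cell_area = 0.09,
                         period = c(2001L, 2020L), with_burn = TRUE,
                         p_loss = 0.3, p_gain = 0.4) {
  set.seed(seed)
  lv <- forest_type_levels()
  ft <- matrix(sample(lv, h * w, replace = TRUE), h, w)
  agc <- matrix(stats::runif(h * w, 10, 300), h, w)
  agc[ft == "nonforest"] <- 0
  loss <- matrix(NA_integer_, h, w)
  cand <- which(ft != "nonforest" & stats::runif(h * w) < p_loss)
  loss[cand] <- sample((period[1] + 1L):period[2], length(cand), replace = TRUE)
  gain <- matrix(FALSE, h, w)
  gain[ft == "nonforest"] <- stats::runif(sum(ft == "nonforest")) < p_gain
  ml <- matrix(stats::runif(h * w) < 0.8, h, w)
  mf <- ml & matrix(stats::runif(h * w) < 0.7, h, w)
  alt <- matrix(sample(lv, h * w, replace = TRUE), h, w)
  biome <- matrix(sample(1:3, h * w, replace = TRUE), h, w)
  peat <- matrix(stats::runif(h * w) < 0.2, h, w)
  burn <- if (with_burn) matrix(stats::runif(h * w) < 0.15, h, w) else NULL
  grid_stack(ft, agc, loss, gain, ml, mf, alt, biome, peat, burn = burn,
             cell_area = cell_area, period = period)
}

# Brute-force oracle: explicit per-cell loop over the documented formulas,
# independent of the vectorized engine path.
oracle_ledger <- function(stack, factors, options = gainloss_options()) {
  n <- stack$period[2] - stack$period[1] + 1
  start <- stack$period[1]; end <- stack$period[2]
  a <- stack$cell_area
  pools <- 1 + factors$root_shoot_ratio + factors$deadwood_ratio +
    factors$litter_ratio
  acc <- new.env()
  book <- function(region, cat, ft, comp, v) {
    key <- paste(region, cat, ft, comp, sep = "\r")
    acc[[key]] <- (acc[[key]] %||% 0) + v
  }
  rf_of <- function(biome, ft) {
    resolve_removal_factor(factors, biome, ft)
  }
  dims <- dim(stack$agc_t0)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    ft <- stack$forest_type_t0[i, j]
    loss <- stack$loss_year[i, j]
    gain <- stack$gain_flag[i, j]
    reg <- paste0("biome_", stack$biome[i, j])
    cat_ <- classify_transition(ft, loss, gain,
                                options$treat_tree_crops_as_cropland)
    if (!is.na(loss)) {
      e <- a * (stack$agc_t0[i, j] * pools +
                  factors$soil_emission * options$include_soil) * 44 / 12 / n
      book(reg, cat_, ft, "emission_deforestation", e)
    }
    if (ft != "nonforest") {
      yrs <- if (is.na(loss)) n else loss - start
      if (!options$removals_on_loss_cells && !is.na(loss)) yrs <- 0
      v <- -a * rf_of(paste0("biome_", stack$biome[i, j]), ft) * 44 / 12 * yrs / n
      if (v != 0) book(reg, cat_, ft, "removal", v)
    }
    if (ft == "nonforest" && gain && options$gain_accrual_fraction > 0) {
      v <- -a * rf_of(reg, "young_secondary") * 44 / 12 *
        options$gain_accrual_fraction
      book(reg, cat_, "young_secondary", "removal", v)
    }
    if (options$include_peat && factors$peat_decomposition > 0 &&
        stack$peat[i, j] && !is.na(loss)) {
      book(reg, cat_, ft, "emission_peat_decomposition",
           factors$peat_decomposition * a * (end - loss + 1) / n)
    }
    burn <- !is.null(stack$burn) && stack$burn[i, j]
    if (options$include_peat && factors$peat_fire > 0 && stack$peat[i, j] &&
        burn && !is.na(cat_)) {
      book(reg, cat_, ft, "emission_peat_fire", factors$peat_fire * a / n)
    }
    if (factors$flfl_burn_emission > 0 && burn && !is.na(cat_) &&
        cat_ == "FL_FL") {
      book(reg, cat_, ft, "emission_flfl_burning",
           factors$flfl_burn_emission * a / n)
    }
  }
  keys <- ls(acc)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  tibble::tibble(region = parts[, 1], category = parts[, 2],
                 forest_type = parts[, 3], component = parts[, 4],
                 value = vapply(keys, function(k) acc[[k]], numeric(1),
                                USE.NAMES = FALSE)) |>
    dplyr::arrange(region, category, forest_type, component)
}

expect_ledger_equal <- function(led, oracle, tol = 1e-9) {
  led <- dplyr::arrange(tibble::as_tibble(led)[names(oracle)],
                        region, category, forest_type, component)
  expect_equal(nrow(led), nrow(oracle))
  expect_identical(led$region, oracle$region)
  expect_identical(led$category, oracle$category)
  expect_identical(led$forest_type, oracle$forest_type)
  expect_identical(led$component, oracle$component)
  expect_lt(max(abs(led$value - oracle$value) /
                  pmax(abs(oracle$value), 1e-12)), tol)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
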