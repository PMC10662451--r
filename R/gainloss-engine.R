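#' Accounting options for the gain-loss engine
#'
#' @param include_soil Book the committed soil-carbon term with deforestation
#'   emissions (off for Brazil-style runs, on for Indonesia/Malaysia-style
#'   runs where mineral/peat soil terms are surfaced).
#' @param include_peat Book peat decomposition (after loss on peat soils) and
#'   peat fire (on burn-flagged peat cells) components.
#' @param treat_tree_crops_as_cropland Map tree crops to the cropland
#'   categories `CL_CL`/`OL_CL` (inventory convention, default) instead of
#'   treating them as plantation forest.
#' @param removals_on_loss_cells Accrue removals on cells up to (exclusive of)
#'   their loss year. If `FALSE`, lost cells carry no removal flux.
#' @param gain_accrual_fraction Fraction of the period over which gained
#'   (other land converted to forest) cells accrue removals; 0.5 represents
#'   mid-period establishment on average.
#' @return A list of class `gainloss_options`.
#' @export
gainloss_options <- function(include_soil = FALSE,
                             include_peat = FALSE,
                             treat_tree_crops_as_cropland = TRUE,
                             removals_on_loss_cells = TRUE,
                             gain_accrual_fraction = 0.5) {
  structure(list(include_soil = include_soil,
                 include_peat = include_peat,
                 treat_tree_crops_as_cropland = treat_tree_crops_as_cropland,
                 removals_on_loss_cells = removals_on_loss_cells,
                 gain_accrual_fraction = gain_accrual_fraction),
            class = "gainloss_options")
}

#' Classify a cell-period into an IPCC transition category
#'
#' Forest at the period start with stand-replacing loss maps to `FL_OL`;
#' forest without loss to `FL_FL`; nonforest with gain to `OL_FL`. Under the
#' cropland convention tree crops map to `CL_CL` (or `OL_CL` when the gain
#' flag marks establishment during the period). Nonforest cells without gain
#' fall outside the accounting boundary and return `NA`.
#'
#' @param forest_type Character vector over [forest_type_levels()].
#' @param loss_year Integer vector of loss years, `NA` = no loss.
#' @param gain_flag Logical vector: forest gain during the period.
#' @param treat_tree_crops_as_cropland Cropland convention flag.
#' @return Character vector over [ipcc_categories()] (NA outside boundary).
#' @examples
#' classify_transition("primary_old_growth", 2005L, FALSE)      # FL_OL
#' classify_transition("nonforest", NA, TRUE)                   # OL_FL
#' classify_transition("tree_crop", NA, FALSE)                  # CL_CL
#' @export
classify_transition <- function(forest_type, loss_year = NA_integer_,
                                gain_flag = FALSE,
                                treat_tree_crops_as_cropland = TRUE) {
  .assert_forest_type(forest_type)
  k <- max(length(forest_type), length(loss_year), length(gain_flag))
  ft <- rep_len(forest_type, k)
  loss <- rep_len(loss_year, k)
  gain <- rep_len(gain_flag, k)
  if (any(ft == "nonforest" & !is.na(loss))) {
    stop("data error: forest loss recorded on nonforest cell", call. = FALSE)
  }
  out <- rep(NA_character_, k)
  nf <- ft == "nonforest"
  out[nf & gain] <- "OL_FL"
  tc <- ft == "tree_crop" & treat_tree_crops_as_cropland
  out[tc] <- ifelse(gain[tc], "OL_CL", "CL_CL")
  fo <- !nf & !tc
  out[fo] <- ifelse(!is.na(loss[fo]), "FL_OL", ifelse(gain[fo], "OL_FL", "FL_FL"))
  out
}

#' Committed emission from stand-replacing loss
#'
#' Expands aboveground carbon to the major carbon pools with the IPCC default
#' ratios (roots, dead wood, litter as fixed ratios of AGC), optionally adds
#' the committed soil term, and converts to CO2:
#' `area * (agc * (1 + rs + dw + lit) + soil * include_soil) * 44/12`.
#'
#' @param agc Aboveground carbon density, Mg C/ha (vectorized).
#' @param factors A [factor_table].
#' @param area Cell area, ha.
#' @param include_soil Include the committed soil-carbon term.
#' @return Committed emission, Mg CO2 (non-negative).
#' @export
committed_emission <- function(agc, factors, area, include_soil = FALSE) {
  if (any(agc < 0, na.rm = TRUE)) {
    stop("data error: negative AGC", call. = FALSE)
  }
  if (any(area <= 0)) stop("data error: area must be > 0", call. = FALSE)
  pools <- 1 + factors$root_shoot_ratio + factors$deadwood_ratio +
    factors$litter_ratio
  area * (agc * pools + factors$soil_emission * as.numeric(include_soil)) *
    factors$co2_per_c
}

#' Average-annual removal flux for one cell
#'
#' Applies the stratum removal factor for the years the cell was forested
#' within the period: a cell lost in year `y` accrues removals for
#' `y - period_start` years; an unlost cell for the whole period. Returned as
#' a (non-positive) average-annual flux:
#' `-area * RF * 44/12 * years_forested / period_length`.
#'
#' @param forest_type,biome Stratum of the cell (vectorized).
#' @param loss_year Loss year or `NA`.
#' @param factors A [factor_table].
#' @param area Cell area, ha.
#' @param period Integer `c(start, end)`, years inclusive.
#' @return Removal flux, Mg CO2/yr (<= 0).
#' @export
removal_flux <- function(forest_type, biome, loss_year, factors, area, period) {
  rf <- resolve_removal_factor(factors, biome, forest_type)
  n <- period_length(period)
  years <- ifelse(is.na(loss_year), n, loss_year - period[1])
  if (any(years < 0 | years > n)) {
    stop("data error: loss_year outside the accounting period", call. = FALSE)
  }
  -area * rf * .CO2_PER_C * years / n
}

#' Unit conversions used in flux accounting
#'
#' @param x Numeric vector (Mg C for `c_to_co2`, Mg biomass for
#'   `biomass_to_c`).
#' @param mode `"c_to_co2"` multiplies by 44/12; `"biomass_to_c"` multiplies
#'   by `carbon_fraction`.
#' @param carbon_fraction Biomass carbon fraction (default 0.47).
#' @return Converted numeric vector.
#' @examples
#' convert_units(12, "c_to_co2")       # 44
#' convert_units(100, "biomass_to_c")  # 47
#' @export
convert_units <- function(x, mode = c("c_to_co2", "biomass_to_c"),
                          carbon_fraction = 0.47) {
  mode <- match.arg(mode)
  if (mode == "c_to_co2") x * .CO2_PER_C else x * carbon_fraction
}

# Per-cell component fluxes (Mg CO2e/yr, average-annual), one row per
# nonzero (cell, component). The engine, the adjustments and their
# complements all aggregate this one table.
cell_fluxes <- function(stack, factors, options = gainloss_options()) {
  validate_grid_stack(stack)
  ft <- as.vector(stack$forest_type_t0)
  agc <- as.vector(stack$agc_t0)
  loss <- as.vector(stack$loss_year)
  gain <- as.vector(stack$gain_flag)
  biome <- as.vector(stack$biome)
  peat <- as.vector(stack$peat)
  burn <- if (is.null(stack$burn)) rep(FALSE, length(ft)) else as.vector(stack$burn)
  area <- stack$cell_area
  n <- period_length(stack$period)
  start <- stack$period[1]; end <- stack$period[2]

  cat_ <- classify_transition(ft, loss, gain,
                              options$treat_tree_crops_as_cropland)
  region <- paste0("biome_", biome)

  rows <- list()
  add <- function(idx, component, value, type = ft[idx]) {
    keep <- value != 0
    if (!any(keep)) return()
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      cell = idx[keep], region = region[idx][keep], category = cat_[idx][keep],
      forest_type = type[keep], component = component, value = value[keep])
  }

  # committed deforestation emissions, annualized over the period
  lost <- which(!is.na(loss))
  if (length(lost)) {
    add(lost, "emission_deforestation",
        committed_emission(agc[lost], factors, area, options$include_soil) / n)
  }

  # removals: forest strata accrue up to loss (or the whole period); gained
  # cells are young regrowth by construction and accrue a period fraction
  forest <- which(ft != "nonforest")
  if (length(forest)) {
    v <- removal_flux(ft[forest], biome[forest], loss[forest], factors, area,
                      stack$period)
    if (!options$removals_on_loss_cells) v[!is.na(loss[forest])] <- 0
    add(forest, "removal", v)
  }
  gained <- which(ft == "nonforest" & gain)
  if (length(gained) && options$gain_accrual_fraction > 0) {
    rf <- resolve_removal_factor(factors, biome[gained],
                                 rep("young_secondary", length(gained)))
    add(gained, "removal",
        -area * rf * .CO2_PER_C * options$gain_accrual_fraction,
        type = rep("young_secondary", length(gained)))
  }

  if (options$include_peat && factors$peat_decomposition > 0) {
    pd <- which(peat & !is.na(loss))
    if (length(pd)) {
      add(pd, "emission_peat_decomposition",
          factors$peat_decomposition * area * (end - loss[pd] + 1) / n)
    }
  }
  # peat fires are booked only inside the accounting boundary (cells with a
  # forest-related transition category)
  if (options$include_peat && factors$peat_fire > 0) {
    pf <- which(peat & burn & !is.na(cat_))
    if (length(pf)) {
      add(pf, "emission_peat_fire",
          rep(factors$peat_fire * area / n, length(pf)))
    }
  }
  if (factors$flfl_burn_emission > 0) {
    fb <- which(burn & !is.na(cat_) & cat_ == "FL_FL")
    if (length(fb)) {
      add(fb, "emission_flfl_burning",
          rep(factors$flfl_burn_emission * area / n, length(fb)))
    }
  }

  if (!length(rows)) {
    return(tibble::tibble(cell = integer(), region = character(),
                          category = character(), forest_type = character(),
                          component = character(), value = numeric()))
  }
  dplyr::bind_rows(rows)
}

.aggregate_ledger <- function(cf, period, provenance) {
  led <- cf |>
    dplyr::group_by(.data$region, .data$category, .data$forest_type,
                    .data$component) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$region, .data$category, .data$forest_type,
                   .data$component)
  led$period_start <- period[1]
  led$period_end <- period[2]
  led$provenance <- provenance
  class(led) <- c("flux_ledger", class(led))
  led
}

#' Run the per-pixel gain-loss accounting over a stack
#'
#' Applies [committed_emission()] (annualized, booked to the cell's category,
#' forest type and biome under `emission_deforestation`), [removal_flux()],
#' and the optional peat and forest-remaining-forest burning components to
#' every cell, and aggregates them into a component-labelled flux ledger of
#' average-annual Mg CO2e/yr.
#'
#' @param stack A [grid_stack].
#' @param factors A [factor_table].
#' @param options A [gainloss_options] list.
#' @return A `flux_ledger` tibble with columns `region`, `category`,
#'   `forest_type`, `component`, `value` (Mg CO2e/yr), `period_start`,
#'   `period_end`, `provenance`.
#' @export
run_gain_loss <- function(stack, factors, options = gainloss_options()) {
  cf <- cell_fluxes(stack, factors, options)
  .aggregate_ledger(cf[setdiff(names(cf), "cell")], stack$period, "unadjusted")
}

#' Ledger summaries
#'
#' `net_flux()` is the algebraic sum of all rows; `gross_emissions()` and
#' `gross_removals()` sum the positive (emission) and non-positive (removal)
#' components respectively; `ledger_total()` aggregates over chosen keys.
#'
#' @param ledger A `flux_ledger`.
#' @param by Character vector of grouping columns for `ledger_total()`.
#' @return Numeric scalar, or a tibble for `ledger_total()`.
#' @export
net_flux <- function(ledger) sum(ledger$value)

#' @rdname net_flux
#' @export
gross_emissions <- function(ledger) {
  sum(ledger$value[ledger$component != "removal"])
}

#' @rdname net_flux
#' @export
gross_removals <- function(ledger) {
  sum(ledger$value[ledger$component == "removal"])
}

#' @rdname net_flux
#' @export
ledger_total <- function(ledger, by = "component") {
  dplyr::summarise(dplyr::group_by(ledger, dplyr::across(dplyr::all_of(by))),
                   value = sum(.data$value), .groups = "drop")
}

#' @export
print.flux_ledger <- function(x, ...) {
  cat(sprintf("<flux_ledger> %s, %d-%d: net %.4g Mg CO2e/yr (E %.4g, R %.4g), %d rows\n",
              x$provenance[1] %||% "empty", x$period_start[1] %||% NA,
              x$period_end[1] %||% NA, net_flux(x), gross_emissions(x),
              gross_removals(x), nrow(x)))
  NextMethod()
}
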