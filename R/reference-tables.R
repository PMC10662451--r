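#' Packaged inventory-comparison reference tables
#'
#' Small transcriptions of the published comparison inputs used by the
#' worked examples and the acceptance checks:
#'
#' * `ref_oldgrowth_factors()` - old-growth removal factors per Brazilian
#'   biome: the single biome-specific inventory factor, the modal
#'   earth-observation factor (with the secondary factor also present in the
#'   biome), the factor used in the printed comparison, and the printed
#'   percentage difference.
#' * `ref_planted_secondary_factors()` - plantation, young-secondary and
#'   old-secondary removal factors per biome with ranges, printed percentage
#'   differences and the decimals each stratum is reported at.
#' * `ref_area_removals_brazil()` - 2020 forest-type areas (thousand ha) and
#'   average-annual gross removals (Gt CO2/yr) per dataset for Brazil.
#' * `ref_land_areas_seasia()` - Indonesian and Malaysian land-type areas
#'   (thousand ha) per dataset, with wetness (dry/swamp) and land-group
#'   labels.
#' * `ref_factors_seasia()` - Indonesian and Malaysian primary-forest
#'   emission factors and removal factors; rows flagged
#'   `converted_from_biomass` were published in biomass units and converted
#'   to carbon with the 0.47 carbon fraction.
#'
#' @return A tibble.
#' @name reference_tables
NULL

.ref_csv <- function(name) {
  path <- system.file("extdata", name, package = "fluxgap", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
}

#' @rdname reference_tables
#' @export
ref_oldgrowth_factors <- function() .ref_csv("brazil_oldgrowth_removal_factors.csv")

#' @rdname reference_tables
#' @export
ref_planted_secondary_factors <- function() {
  .ref_csv("brazil_planted_secondary_removal_factors.csv")
}

#' @rdname reference_tables
#' @export
ref_area_removals_brazil <- function() .ref_csv("brazil_forest_area_removals_2020.csv")

#' @rdname reference_tables
#' @export
ref_land_areas_seasia <- function() .ref_csv("seasia_land_areas.csv")

#' @rdname reference_tables
#' @export
ref_factors_seasia <- function() .ref_csv("seasia_emission_removal_factors.csv")
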