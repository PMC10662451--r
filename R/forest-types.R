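#' Forest type vocabulary
#'
#' The six land-cover classes used throughout the package. `primary_old_growth`
#' is undisturbed old-growth forest; `old_secondary` is naturally regenerating
#' forest older than 20 years; `young_secondary` is regrowth younger than 20
#' years; `plantation_forest` and `tree_crop` are planted classes (tree crops
#' such as oil palm are treated as cropland by inventory convention); and
#' `nonforest` is everything else.
#'
#' @return Character vector of the six class names, in code order.
#' @export
forest_type_levels <- function() {
  c("primary_old_growth", "old_secondary", "young_secondary",
    "plantation_forest", "tree_crop", "nonforest")
}

# integer codes used on disk and in categorical layers
.ft_codes <- function() stats::setNames(seq_len(6L), forest_type_levels())

#' IPCC transition categories
#'
#' Land-use transition categories in the gain-loss accounting frame:
#' forest land remaining forest land (`FL_FL`), forest land converted to other
#' land (`FL_OL`), other land converted to forest land (`OL_FL`), and the
#' cropland-convention categories used for tree crops (`CL_CL`, `OL_CL`).
#'
#' @return Character vector of category codes.
#' @export
ipcc_categories <- function() c("FL_FL", "FL_OL", "OL_FL", "CL_CL", "OL_CL")

#' Flux components booked by the gain-loss engine
#'
#' @return Character vector of component names. Emission components are
#'   non-negative, the `removal` component is non-positive.
#' @export
flux_components <- function() {
  c("emission_deforestation", "emission_flfl_burning",
    "emission_peat_decomposition", "emission_peat_fire", "removal")
}

# stoichiometric constant: Mg CO2 per Mg C
.CO2_PER_C <- 44 / 12

# nodata sentinel for categorical bands on disk
.NODATA_CAT <- 255L

# forest classes at t0 (everything that can carry AGC and lose forest)
.forest_classes <- function() setdiff(forest_type_levels(), "nonforest")

.assert_forest_type <- function(x, arg = "forest_type") {
  bad <- !x %in% forest_type_levels() & !is.na(x)
  if (any(bad)) {
    stop(sprintf("unknown %s: %s", arg,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Reported percentage differences and ratios use commercial ("half-up")
#' rounding, i.e. ties round away from zero, unlike [base::round()]'s
#' round-half-even. `round_half_up(-12.5, 0)` is -13.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
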