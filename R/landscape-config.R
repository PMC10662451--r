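#' Configuration for the synthetic landscape generator
#'
#' Describes a seeded synthetic tropical-country landscape: a mosaic of
#' contiguous patches of primary old-growth forest, secondary regrowth,
#' plantations, tree crops and nonforest, with stochastic forest loss over a
#' multi-year period, an inventory-style managed-land mask that partially
#' disagrees with the primary-forest extent, and a second classification layer
#' with configurable confusion against the first.
#'
#' Defaults emulate a Brazil-like study region: 20-year period, 0.09 ha cells
#' (~30 m pixels), a landscape dominated by primary forest with about half of
#' it inside one contiguous unmanaged block, skewed (lognormal) aboveground
#' carbon densities that are highest in old-growth and lowest in young
#' regrowth, low annual loss probabilities, and a second classification that
#' relabels most old-secondary cells (emulating an inventory that maps them as
#' managed old-growth).
#'
#' @param grid_height,grid_width Grid dimensions in cells.
#' @param cell_area Cell area in hectares (default 0.09, a 30 m pixel).
#' @param period Integer vector `c(start, end)` of calendar years, inclusive.
#' @param class_proportions Named numeric over [forest_type_levels()], summing
#'   to 1: target share of cells per class.
#' @param agc_distributions Named list per class; each element is
#'   `list(family = "lognormal", meanlog =, sdlog =)` or
#'   `list(family = "constant", value =)`, in Mg C/ha.
#' @param annual_loss_prob Named numeric per class: annual probability that a
#'   cell of that class experiences stand-replacing loss. Must be 0 for
#'   `nonforest`.
#' @param gain_prob Probability (over the whole period) that a nonforest cell
#'   registers forest gain.
#' @param unmanaged_block_fraction Fraction of primary-forest cells placed in
#'   one contiguous unmanaged block (0 = everything managed).
#' @param confusion_rates Named numeric per class: probability that the second
#'   classification layer relabels a cell of that class. Relabels draw the new
#'   class from the remaining classes proportionally to `class_proportions`.
#' @param peat_fraction Fraction of rows (from the grid bottom) flagged as
#'   peat soil.
#' @param biome_count Number of vertical biome bands.
#' @param patch_target Target patch size in cells for the region-growing class
#'   map (larger = coarser, more spatially autocorrelated mosaics).
#' @param seed Integer seed; drives every random layer through deterministic
#'   per-layer sub-streams.
#' @return A `landscape_config` object (validated list).
#' @seealso [generate_landscape()]
#' @export
landscape_config <- function(grid_height,
                             grid_width = grid_height,
                             cell_area = 0.09,
                             period = c(2001L, 2020L),
                             class_proportions = c(
                               primary_old_growth = 0.40, old_secondary = 0.18,
                               young_secondary = 0.07, plantation_forest = 0.06,
                               tree_crop = 0.04, nonforest = 0.25),
                             agc_distributions = default_agc_distributions(),
                             annual_loss_prob = c(
                               primary_old_growth = 0.004, old_secondary = 0.008,
                               young_secondary = 0.012, plantation_forest = 0.02,
                               tree_crop = 0.01, nonforest = 0),
                             gain_prob = 0.2,
                             unmanaged_block_fraction = 0.5,
                             confusion_rates = c(
                               primary_old_growth = 0.02, old_secondary = 0.65,
                               young_secondary = 0.35, plantation_forest = 0.05,
                               tree_crop = 0.10, nonforest = 0.02),
                             peat_fraction = 0,
                             biome_count = 3L,
                             patch_target = 64L,
                             seed = 1L) {
  cfg <- list(
    grid_height = as.integer(grid_height), grid_width = as.integer(grid_width),
    cell_area = cell_area, period = as.integer(period),
    class_proportions = class_proportions[forest_type_levels()],
    agc_distributions = agc_distributions,
    annual_loss_prob = annual_loss_prob[forest_type_levels()],
    gain_prob = gain_prob,
    unmanaged_block_fraction = unmanaged_block_fraction,
    confusion_rates = confusion_rates[forest_type_levels()],
    peat_fraction = peat_fraction,
    biome_count = as.integer(biome_count),
    patch_target = as.integer(patch_target),
    seed = as.integer(seed))
  class(cfg) <- "landscape_config"
  validate_landscape_config(cfg)
}

#' Default per-class aboveground carbon distributions (Mg C/ha)
#'
#' Lognormal per forest class with the old-growth median highest, plantations
#' and tree crops intermediate and young regrowth lowest; nonforest is
#' constant zero.
#'
#' @return Named list of distribution specs.
#' @export
default_agc_distributions <- function() {
  list(
    primary_old_growth = list(family = "lognormal", meanlog = log(150), sdlog = 0.30),
    old_secondary      = list(family = "lognormal", meanlog = log(90),  sdlog = 0.35),
    young_secondary    = list(family = "lognormal", meanlog = log(30),  sdlog = 0.40),
    plantation_forest  = list(family = "lognormal", meanlog = log(55),  sdlog = 0.35),
    tree_crop          = list(family = "lognormal", meanlog = log(40),  sdlog = 0.30),
    nonforest          = list(family = "constant",  value = 0))
}

#' @rdname landscape_config
#' @param config Object to validate.
#' @export
validate_landscape_config <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "landscape_config"))
  if (cfg$grid_height < 1L || cfg$grid_width < 1L) {
    stop("configuration error: grid dimensions must be positive", call. = FALSE)
  }
  if (!is.finite(cfg$cell_area) || cfg$cell_area <= 0) {
    stop("configuration error: cell_area must be > 0", call. = FALSE)
  }
  if (length(cfg$period) != 2L || cfg$period[2] <= cfg$period[1]) {
    stop("configuration error: period_end must be after period_start", call. = FALSE)
  }
  p <- cfg$class_proportions
  if (anyNA(p) || !setequal(names(p), forest_type_levels())) {
    stop("configuration error: class_proportions must name all forest types",
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("configuration error: class_proportions must sum to 1", call. = FALSE)
  }
  probs <- c(cfg$annual_loss_prob, cfg$confusion_rates, cfg$gain_prob,
             cfg$unmanaged_block_fraction, cfg$peat_fraction)
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$annual_loss_prob[["nonforest"]] != 0) {
    stop("configuration error: nonforest cells cannot have loss probability",
         call. = FALSE)
  }
  for (ft in forest_type_levels()) {
    d <- cfg$agc_distributions[[ft]]
    if (is.null(d) || !d$family %in% c("lognormal", "constant")) {
      stop(sprintf("configuration error: missing/unknown AGC distribution for %s", ft),
           call. = FALSE)
    }
  }
  if (cfg$biome_count < 1L) {
    stop("configuration error: biome_count must be >= 1", call. = FALSE)
  }
  cfg
}

#' @export
print.landscape_config <- function(x, ...) {
  cat(sprintf("<landscape_config> %d x %d cells (%.2f ha each), %d-%d, seed %d\n",
              x$grid_height, x$grid_width, x$cell_area,
              x$period[1], x$period[2], x$seed))
  cat("  proportions:",
      paste(sprintf("%s=%.2f", names(x$class_proportions), x$class_proportions),
            collapse = " "), "\n")
  invisible(x)
}
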