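#' Emission/removal factor table
#'
#' Carries the per-stratum removal factors and the carbon-pool constants used
#' by the gain-loss engine: removal factors (Mg C/ha/yr) resolved by
#' (biome, forest type) with optional min/max ranges; the root-to-shoot,
#' deadwood and litter expansion ratios applied to aboveground carbon when
#' booking committed loss emissions; optional soil and peat terms; and the
#' biomass-to-carbon and C-to-CO2 conversion constants.
#'
#' A biome entry of `"*"` in `removal_factors` matches any biome, so a single
#' row per forest type defines a biome-independent (Tier-1 style) factor set.
#'
#' @param removal_factors Data frame with columns `biome`, `forest_type`,
#'   `rf_central` and optionally `rf_min`, `rf_max` (Mg C/ha/yr).
#' @param root_shoot_ratio Belowground:aboveground biomass ratio.
#' @param deadwood_ratio,litter_ratio Dead wood and litter pools as fractions
#'   of AGC.
#' @param soil_emission Mg C/ha committed on loss when soil is included.
#' @param peat_decomposition Mg CO2e/ha/yr emitted by drained peat after loss.
#' @param peat_fire Mg CO2e/ha per peat burn event.
#' @param flfl_burn_emission Mg CO2e/ha per burn event on forest remaining
#'   forest.
#' @param carbon_fraction Biomass-to-carbon conversion constant (default 0.47).
#' @return A `factor_table` object.
#' @export
factor_table <- function(removal_factors,
                         root_shoot_ratio = 0.26,
                         deadwood_ratio = 0.08,
                         litter_ratio = 0.04,
                         soil_emission = 0,
                         peat_decomposition = 0,
                         peat_fire = 0,
                         flfl_burn_emission = 0,
                         carbon_fraction = 0.47) {
  rf <- tibble::as_tibble(removal_factors)
  stopifnot(all(c("biome", "forest_type", "rf_central") %in% names(rf)))
  if (!"rf_min" %in% names(rf)) rf$rf_min <- NA_real_
  if (!"rf_max" %in% names(rf)) rf$rf_max <- NA_real_
  rf$biome <- as.character(rf$biome)
  .assert_forest_type(rf$forest_type)
  x <- structure(list(
    removal_factors = rf,
    root_shoot_ratio = root_shoot_ratio,
    deadwood_ratio = deadwood_ratio,
    litter_ratio = litter_ratio,
    soil_emission = soil_emission,
    peat_decomposition = peat_decomposition,
    peat_fire = peat_fire,
    flfl_burn_emission = flfl_burn_emission,
    carbon_fraction = carbon_fraction,
    co2_per_c = .CO2_PER_C), class = "factor_table")
  validate_factor_table(x)
}

#' @rdname factor_table
#' @param x Object to validate.
#' @export
validate_factor_table <- function(x) {
  stopifnot(inherits(x, "factor_table"))
  vals <- c(x$removal_factors$rf_central, x$root_shoot_ratio, x$deadwood_ratio,
            x$litter_ratio, x$soil_emission, x$peat_decomposition, x$peat_fire,
            x$flfl_burn_emission)
  if (any(vals < 0, na.rm = TRUE)) {
    stop("configuration error: factors must be non-negative", call. = FALSE)
  }
  if (x$carbon_fraction <= 0 || x$carbon_fraction >= 1) {
    stop("configuration error: carbon_fraction must lie in (0, 1)", call. = FALSE)
  }
  key <- paste(x$removal_factors$biome, x$removal_factors$forest_type)
  if (anyDuplicated(key)) {
    stop("configuration error: duplicate (biome, forest_type) removal factor",
         call. = FALSE)
  }
  x
}

#' Resolve removal factors for (biome, forest type) strata
#'
#' Exact `(biome, forest_type)` rows take precedence over `("*", forest_type)`
#' wildcard rows. Every requested stratum must resolve to exactly one factor.
#'
#' @param factors A [factor_table].
#' @param biome Character vector of biome labels.
#' @param forest_type Character vector of forest types (recycled with biome).
#' @return Numeric vector of central removal factors (Mg C/ha/yr).
#' @export
resolve_removal_factor <- function(factors, biome, forest_type) {
  rf <- factors$removal_factors
  key <- paste(as.character(biome), forest_type)
  hit <- match(key, paste(rf$biome, rf$forest_type))
  wild <- match(paste("*", forest_type), paste(rf$biome, rf$forest_type))
  hit[is.na(hit)] <- wild[is.na(hit)]
  if (anyNA(hit)) {
    miss <- unique(key[is.na(hit)])
    stop(sprintf("configuration error: no removal factor for stratum %s",
                 paste(miss, collapse = "; ")), call. = FALSE)
  }
  rf$rf_central[hit]
}

#' Biome-independent default factor set for synthetic tropical landscapes
#'
#' Central removal factors in line with tropical inventory practice: slow
#' old-growth uptake, moderate regrowth in old secondary forest, fast uptake
#' in young secondary forest and plantations, and an oil-palm-like rate for
#' tree crops.
#'
#' @inheritParams factor_table
#' @param ... Passed on to [factor_table()] to override pool ratios or peat
#'   terms.
#' @return A [factor_table].
#' @export
tropical_default_factors <- function(...) {
  rf <- tibble::tibble(
    biome = "*",
    forest_type = c("primary_old_growth", "old_secondary", "young_secondary",
                    "plantation_forest", "tree_crop"),
    rf_central = c(0.59, 1.36, 4.5, 12.7, 3.0),
    rf_min = c(0.24, 0.59, 2.0, 4.72, 1.84),
    rf_max = c(0.95, 1.60, 8.0, 20.3, 3.4))
  factor_table(rf, ...)
}

#' @export
print.factor_table <- function(x, ...) {
  cat(sprintf(
    "<factor_table> %d removal-factor rows; pools: rs=%.2f dw=%.2f lit=%.2f; cf=%.2f\n",
    nrow(x$removal_factors), x$root_shoot_ratio, x$deadwood_ratio,
    x$litter_ratio, x$carbon_fraction))
  print(x$removal_factors, n = 12)
  invisible(x)
}

#' Read/write a factor table (CSV body with a YAML constants header)
#'
#' The on-disk format is a UTF-8 CSV of the removal-factor rows preceded by a
#' commented YAML block (lines starting `# `) holding the pool ratios and
#' constants, delimited by `# ---` lines.
#'
#' @param path File path.
#' @param factors A [factor_table] (for writing).
#' @return `read_factor_table()` returns a [factor_table];
#'   `write_factor_table()` returns `path` invisibly.
#' @export
write_factor_table <- function(factors, path) {
  consts <- factors[c("root_shoot_ratio", "deadwood_ratio", "litter_ratio",
                      "soil_emission", "peat_decomposition", "peat_fire",
                      "flfl_burn_emission", "carbon_fraction")]
  hdr <- c("# ---", paste0("# ", strsplit(yaml::as.yaml(consts), "\n")[[1]]), "# ---")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(factors$removal_factors, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_factor_table
#' @export
read_factor_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^# ---", lines)
  consts <- list()
  body <- lines
  if (length(hdr) >= 2) {
    yml <- sub("^# ?", "", lines[(hdr[1] + 1):(hdr[2] - 1)])
    consts <- yaml::yaml.load(paste(yml, collapse = "\n"))
    body <- lines[-seq_len(hdr[2])]
  }
  rf <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  do.call(factor_table, c(list(removal_factors = rf), consts))
}
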