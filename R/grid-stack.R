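#' Aligned raster layers describing one landscape and its change
#'
#' A `grid_stack` bundles the aligned single-band layers the gain-loss engine
#' consumes: the forest-type map at the period start, aboveground carbon
#' density (AGC, Mg C/ha), the year of stand-replacing loss (NA = no loss),
#' a forest-gain flag, managed-land and managed-forest masks, a second
#' (inventory-style) classification, a biome band and a peat-soil flag.
#' Matrices are row-major with the origin at the top-left.
#'
#' @param forest_type_t0,alt_class Character matrices over
#'   [forest_type_levels()] (the constructor also accepts integer code
#'   matrices).
#' @param agc_t0 Numeric matrix, Mg C/ha, non-negative; zero on nonforest.
#' @param loss_year Integer matrix of calendar years in
#'   `(period[1], period[2]]`, NA where no loss occurred.
#' @param gain_flag Logical matrix: forest gain during the period.
#' @param managed_land,managed_forest Logical masks (`managed_forest` must be
#'   a subset of `managed_land`); either may be NULL when a stack is built
#'   from partial data, in which case adjustments requiring them fail.
#' @param biome Integer matrix of biome codes (>= 1).
#' @param peat Logical matrix: organic (peat) soils.
#' @param burn Optional logical matrix of burn events (default NULL = none).
#' @param cell_area Cell area in hectares.
#' @param period Integer `c(start, end)`, calendar years inclusive.
#' @return A validated `grid_stack` object.
#' @export
grid_stack <- function(forest_type_t0, agc_t0, loss_year, gain_flag,
                       managed_land, managed_forest, alt_class, biome, peat,
                       burn = NULL, cell_area, period) {
  to_ft <- function(m) {
    if (is.numeric(m)) {
      out <- matrix(forest_type_levels()[m], nrow(m), ncol(m))
      if (anyNA(out) && !all(is.na(m[is.na(out)]))) {
        stop("data error: unknown forest type code", call. = FALSE)
      }
      out
    } else {
      .assert_forest_type(as.vector(m))
      m
    }
  }
  x <- structure(list(
    forest_type_t0 = to_ft(forest_type_t0),
    agc_t0 = agc_t0,
    loss_year = loss_year,
    gain_flag = gain_flag,
    managed_land = managed_land,
    managed_forest = managed_forest,
    alt_class = to_ft(alt_class),
    biome = biome,
    peat = peat,
    burn = burn,
    cell_area = cell_area,
    period = as.integer(period)), class = "grid_stack")
  validate_grid_stack(x)
}

.stack_layer_names <- function(x) {
  nm <- c("forest_type_t0", "agc_t0", "loss_year", "gain_flag",
          "managed_land", "managed_forest", "alt_class", "biome", "peat", "burn")
  nm[vapply(x[nm], Negate(is.null), logical(1))]
}

#' @rdname grid_stack
#' @param x Object to validate.
#' @export
validate_grid_stack <- function(x) {
  stopifnot(inherits(x, "grid_stack"))
  dims <- lapply(x[.stack_layer_names(x)], dim)
  if (length(unique(dims)) != 1L) {
    stop("data error: stack layers have mismatched dimensions", call. = FALSE)
  }
  if (!is.finite(x$cell_area) || x$cell_area <= 0) {
    stop("data error: cell_area must be > 0", call. = FALSE)
  }
  if (x$period[2] <= x$period[1]) {
    stop("data error: period end must be after period start", call. = FALSE)
  }
  if (any(x$agc_t0 < 0, na.rm = TRUE)) {
    stop("data error: negative AGC", call. = FALSE)
  }
  nf <- x$forest_type_t0 == "nonforest"
  if (any(x$agc_t0[nf] != 0)) {
    stop("data error: nonforest cells must have zero AGC", call. = FALSE)
  }
  if (any(!is.na(x$loss_year[nf]))) {
    stop("data error: forest loss recorded on nonforest cells", call. = FALSE)
  }
  ly <- x$loss_year[!is.na(x$loss_year)]
  if (length(ly) && (any(ly <= x$period[1]) || any(ly > x$period[2]))) {
    stop("data error: loss_year outside (period start, period end]", call. = FALSE)
  }
  if (!is.null(x$managed_land) && !is.null(x$managed_forest) &&
      any(x$managed_forest & !x$managed_land)) {
    stop("data error: managed_forest must imply managed_land", call. = FALSE)
  }
  x
}

#' Number of calendar years in a stack period (endpoints inclusive)
#' @param period Integer `c(start, end)`.
#' @return Integer year count.
#' @export
period_length <- function(period) as.integer(period[2] - period[1] + 1L)

#' @export
print.grid_stack <- function(x, ...) {
  d <- dim(x$forest_type_t0)
  cat(sprintf("<grid_stack> %d x %d cells (%.2f ha each), period %d-%d\n",
              d[1], d[2], x$cell_area, x$period[1], x$period[2]))
  tab <- table(factor(x$forest_type_t0, forest_type_levels()))
  cat("  cover:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  cat(sprintf("  loss cells: %d | gain cells: %d | peat cells: %d\n",
              sum(!is.na(x$loss_year)), sum(x$gain_flag), sum(x$peat)))
  invisible(x)
}
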