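# Inventory-comparison statistics: modal factors, percentage differences,
# classification cross-tabulations, mask overlaps, area tables, swamp:dry
# ratios and AGC distribution summaries.

#' Modal value of a factor layer within a stratum
#'
#' The most frequent value among the selected cells; ties break to the
#' smallest value. The result is always a member of the selected value set.
#' Used to summarise the removal factor a gridded dataset effectively applies
#' within an inventory stratum (e.g. a biome).
#'
#' @param factor_layer Numeric matrix/vector of per-cell factors.
#' @param stratum_mask Logical layer selecting at least one cell.
#' @return The modal factor value.
#' @export
modal_factor <- function(factor_layer, stratum_mask) {
  v <- as.vector(factor_layer)[as.vector(stratum_mask)]
  if (!length(v)) stop("empty-stratum error: mask selects no cells", call. = FALSE)
  u <- sort(unique(v))
  counts <- tabulate(match(v, u))
  u[which.max(counts)]  # which.max takes the first (smallest) on ties
}

#' Rounded percentage difference between two factors
#'
#' `round(100 * (candidate - reference) / reference, decimals)` with
#' half-away-from-zero rounding (the convention of printed inventory
#' comparison tables).
#'
#' @param candidate,reference Factors in the same unit; `reference > 0`.
#'   Vectorized.
#' @param decimals Decimal places of the report (0 for old-growth and young
#'   secondary comparisons, 1 for plantations).
#' @return Percentage difference(s).
#' @examples
#' pct_difference(0.59, 0.48)        # +23
#' pct_difference(11.2, 12.5, 1)     # -10.4
#' @export
pct_difference <- function(candidate, reference, decimals = 0) {
  if (any(reference <= 0)) {
    stop("undefined-difference error: reference must be > 0", call. = FALSE)
  }
  round_half_up(100 * (candidate - reference) / reference, decimals)
}

#' Cross-tabulate two classification layers
#'
#' Counts cells per (row class, column class) pair inside an optional mask
#' and row-normalizes to percentages of the first layer's class totals.
#' Rows with zero count are all-zero and flagged in the `zero_rows`
#' attribute.
#'
#' @param map_a,map_b Aligned character (or code) forest-type layers; rows of
#'   the result follow `map_a`.
#' @param mask Optional logical layer restricting the tabulated cells.
#' @param classes Class vocabulary (default [forest_type_levels()]).
#' @return A `cross_tab` object with `counts` and `percentages` matrices.
#' @export
cross_tabulate <- function(map_a, map_b, mask = NULL,
                           classes = forest_type_levels()) {
  if (!identical(dim(map_a), dim(map_b))) {
    stop("data error: classification layers are misaligned", call. = FALSE)
  }
  a <- factor(as.vector(map_a), classes)
  b <- factor(as.vector(map_b), classes)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(map_a))) {
      stop("data error: mask misaligned with classification layers", call. = FALSE)
    }
    keep <- as.vector(mask)
    a <- a[keep]; b <- b[keep]
  }
  counts <- unclass(table(a, b))
  rs <- rowSums(counts)
  pct <- counts * 0
  nz <- rs > 0
  pct[nz, ] <- 100 * counts[nz, , drop = FALSE] / rs[nz]
  structure(list(row_classes = classes, col_classes = classes,
                 counts = counts, percentages = pct,
                 zero_rows = classes[!nz]),
            class = "cross_tab")
}

#' @export
print.cross_tab <- function(x, ...) {
  cat("<cross_tab> row-normalized percentages (rows = first layer)\n")
  print(round(x$percentages, 1))
  if (length(x$zero_rows)) {
    cat("  empty rows:", paste(x$zero_rows, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Percent of one mask covered by another
#'
#' `100 * |a AND b| / |b|`: the share of the second mask's cells that the
#' first mask overlaps (e.g. the share of inventory managed forest that an
#' earth-observation non-primary-forest proxy captures).
#'
#' @param mask_a,mask_b Aligned logical layers; `mask_b` must select at least
#'   one cell.
#' @return Percentage in [0, 100].
#' @export
overlap_percent <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("data error: masks are misaligned", call. = FALSE)
  }
  nb <- sum(mask_b)
  if (nb == 0) stop("empty-denominator error: second mask selects no cells",
                    call. = FALSE)
  100 * sum(mask_a & mask_b) / nb
}

#' Tabulate area by region and type
#'
#' Cell counts times cell area, reported in thousand hectares, grouped by a
#' region layer and a type layer from a stack.
#'
#' @param stack A [grid_stack].
#' @param region_layer,type_layer Names of stack layers to group by.
#' @return Tibble with columns `region`, `type`, `area_kha`.
#' @export
area_table <- function(stack, region_layer = "biome",
                       type_layer = "forest_type_t0") {
  reg <- as.vector(stack[[region_layer]])
  typ <- as.vector(stack[[type_layer]])
  if (length(reg) != length(typ)) {
    stop("data error: grouping layers are misaligned", call. = FALSE)
  }
  df <- tibble::tibble(region = as.character(reg), type = as.character(typ))
  df |>
    dplyr::count(.data$region, .data$type, name = "cells") |>
    dplyr::mutate(area_kha = .data$cells * stack$cell_area / 1000) |>
    dplyr::select(-"cells")
}

#' Ratio of swamp (peatland) to dryland forest area
#'
#' Sums the areas of the rows matching the swamp labels and divides by the
#' summed dryland areas; reported rounded to 2 decimals.
#'
#' @param table Data frame of areas (e.g. from [area_table()] or a packaged
#'   land-area table).
#' @param swamp_labels,dry_labels Values of `label_col` selecting the swamp
#'   and dryland rows (each must match at least one row).
#' @param label_col,area_col Column names holding labels and areas.
#' @return The rounded ratio.
#' @export
swamp_dry_ratio <- function(table, swamp_labels, dry_labels,
                            label_col = "land_type", area_col = "area_kha") {
  pick <- function(labels, what) {
    rows <- table[[label_col]] %in% labels
    if (!any(rows)) {
      stop(sprintf("mapping error: no rows match the %s labels", what),
           call. = FALSE)
    }
    sum(table[[area_col]][rows])
  }
  swamp <- pick(swamp_labels, "swamp")
  dry <- pick(dry_labels, "dry")
  if (dry == 0) stop("undefined-ratio error: dry area is zero", call. = FALSE)
  round_half_up(swamp / dry, 2)
}

#' Summary statistics of aboveground carbon within a stratum
#'
#' Mean, lower quartile, median and upper quartile (type-7 quantiles) of the
#' AGC values under a mask; `iqr_overlap()` reports whether two strata's
#' interquartile ranges intersect.
#'
#' @param stack A [grid_stack] (or a numeric matrix of AGC values).
#' @param stratum_mask Logical layer selecting at least one cell.
#' @return Named numeric `c(mean, q1, median, q3)` in Mg C/ha.
#' @export
agc_summary <- function(stack, stratum_mask) {
  layer <- if (inherits(stack, "grid_stack")) stack$agc_t0 else stack
  v <- as.vector(layer)[as.vector(stratum_mask)]
  if (!length(v)) stop("empty-stratum error: mask selects no cells", call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(mean = mean(v), q1 = q[1], median = q[2], q3 = q[3])
}

#' @rdname agc_summary
#' @param s1,s2 Summaries from [agc_summary()].
#' @export
iqr_overlap <- function(s1, s2) {
  max(s1[["q1"]], s2[["q1"]]) <= min(s1[["q3"]], s2[["q3"]])
}

#' Side-by-side area and gross-removal table per forest type
#'
#' Joins per-dataset columns of area (thousand ha) and gross removals per
#' forest type and appends a `Total` row computed from the unrounded column
#' sums. Input elements are tibbles with columns `forest_type`, `area_kha`
#' and (optionally) `gross_removals`.
#'
#' @param tables Named list of per-dataset tibbles (names become column
#'   prefixes; a `labels` argument may override them).
#' @param labels Optional character vector of dataset labels.
#' @return A wide tibble with one row per forest type plus a `Total` row.
#' @export
removals_by_type_report <- function(tables, labels = names(tables)) {
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("mapping error: each input table needs a label", call. = FALSE)
  }
  types <- unique(unlist(lapply(tables, function(t) t$forest_type)))
  out <- tibble::tibble(forest_type = types)
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    if (!all(c("forest_type", "area_kha") %in% names(t))) {
      stop("mapping error: tables need forest_type and area_kha columns",
           call. = FALSE)
    }
    out[[paste0(labels[i], "_area_kha")]] <- t$area_kha[match(types, t$forest_type)]
    if ("gross_removals" %in% names(t)) {
      out[[paste0(labels[i], "_gross_removals")]] <-
        t$gross_removals[match(types, t$forest_type)]
    }
  }
  totals <- c(forest_type = "Total",
              lapply(out[-1], function(col) sum(col, na.rm = TRUE)))
  dplyr::bind_rows(out, tibble::as_tibble(totals))
}
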