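# Raster stack and table serialization.
#
# Each stack layer is written as a single-band TIFF. TIFF samples are stored
# on a [0, 1] scale, so categorical and year bands are written as scaled
# 8/16-bit integers (exact round-trip) and AGC as 32-bit float divided by a
# scale factor recorded in the sidecar (round-trip within float32 relative
# precision). The sidecar `stack.yml` carries grid geometry, the period, the
# cell area, the category code table and the scale factors.

.LOSS_OFFSET <- 1900L  # loss years stored as year - offset in a 16-bit band

.write_band <- function(m, path, kind, agc_scale = 1) {
  switch(kind,
    cat8 = tiff::writeTIFF(m / 255, path, bits.per.sample = 8,
                           compression = "none"),
    uint16 = tiff::writeTIFF(m / 65535, path, bits.per.sample = 16,
                             compression = "none"),
    float = tiff::writeTIFF(m / agc_scale, path, bits.per.sample = 32,
                            compression = "none"))
  invisible(path)
}

.read_band <- function(path, kind, agc_scale = 1) {
  r <- tiff::readTIFF(path)
  switch(kind,
    cat8 = round(r * 255),
    uint16 = round(r * 65535),
    float = r * agc_scale)
}

#' Write/read a grid stack as single-band TIFF layers plus a YAML sidecar
#'
#' Categorical and boolean layers round-trip bit-exactly; the AGC layer
#' round-trips within float32 relative precision. Nodata sentinels (255 for
#' categorical bands, 0 for the loss-year band) are preserved.
#'
#' @param stack A [grid_stack].
#' @param dir Directory to hold the layer TIFFs and `stack.yml`.
#' @return `read_stack()` returns a [grid_stack]; `write_stack()` returns
#'   `dir` invisibly.
#' @export
write_stack <- function(stack, dir) {
  validate_grid_stack(stack)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  codes <- .ft_codes()
  ft <- matrix(codes[stack$forest_type_t0], nrow(stack$agc_t0))
  alt <- matrix(codes[stack$alt_class], nrow(stack$agc_t0))
  loss <- stack$loss_year - .LOSS_OFFSET
  loss[is.na(loss)] <- 0L
  agc_scale <- max(1, 2^ceiling(log2(max(stack$agc_t0, 1))))

  .write_band(ft, file.path(dir, "forest_type_t0.tif"), "cat8")
  .write_band(alt, file.path(dir, "alt_class.tif"), "cat8")
  .write_band(stack$biome, file.path(dir, "biome.tif"), "cat8")
  .write_band(loss, file.path(dir, "loss_year.tif"), "uint16")
  .write_band(stack$agc_t0, file.path(dir, "agc_t0.tif"), "float", agc_scale)
  for (nm in c("gain_flag", "managed_land", "managed_forest", "peat", "burn")) {
    if (is.null(stack[[nm]])) next
    .write_band(stack[[nm]] + 0L, file.path(dir, paste0(nm, ".tif")), "cat8")
  }
  meta <- list(
    grid = list(height = nrow(stack$agc_t0), width = ncol(stack$agc_t0)),
    cell_area_ha = stack$cell_area,
    period = as.list(stats::setNames(as.integer(stack$period), c("start", "end"))),
    forest_type_codes = as.list(codes),
    nodata_categorical = .NODATA_CAT,
    loss_year = list(offset = .LOSS_OFFSET, sentinel = 0L),
    agc_scale = agc_scale,
    boolean_layers = Filter(function(nm) !is.null(stack[[nm]]),
                            c("gain_flag", "managed_land", "managed_forest",
                              "peat", "burn")))
  yaml::write_yaml(meta, file.path(dir, "stack.yml"))
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta_path <- file.path(dir, "stack.yml")
  if (!file.exists(meta_path)) {
    stop(sprintf("data error: no stack.yml in %s", dir), call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  ft_codes <- unlist(meta$forest_type_codes)
  decode_ft <- function(m) {
    known <- m %in% ft_codes
    if (any(!known)) stop("data error: unknown category code", call. = FALSE)
    matrix(names(ft_codes)[match(m, ft_codes)], nrow(m))
  }
  ft <- decode_ft(.read_band(file.path(dir, "forest_type_t0.tif"), "cat8"))
  alt <- decode_ft(.read_band(file.path(dir, "alt_class.tif"), "cat8"))
  loss <- .read_band(file.path(dir, "loss_year.tif"), "uint16")
  loss[loss == meta$loss_year$sentinel] <- NA_integer_
  loss <- matrix(as.integer(loss + meta$loss_year$offset), nrow(loss))
  agc <- .read_band(file.path(dir, "agc_t0.tif"), "float", meta$agc_scale)
  bools <- stats::setNames(
    lapply(unlist(meta$boolean_layers), function(nm) {
      .read_band(file.path(dir, paste0(nm, ".tif")), "cat8") == 1
    }), unlist(meta$boolean_layers))
  grid_stack(
    forest_type_t0 = ft, agc_t0 = agc, loss_year = loss,
    gain_flag = bools$gain_flag, managed_land = bools$managed_land,
    managed_forest = bools$managed_forest, alt_class = alt,
    biome = matrix(as.integer(.read_band(file.path(dir, "biome.tif"), "cat8")),
                   nrow(agc)),
    peat = bools$peat, burn = bools$burn,
    cell_area = meta$cell_area_ha,
    period = c(meta$period$start, meta$period$end))
}

#' Write/read a flux ledger as CSV
#'
#' Columns: `region`, `category`, `forest_type`, `component`,
#' `value_mg_co2e_per_yr`, `period_start`, `period_end`, `provenance`.
#'
#' @param ledger A `flux_ledger`.
#' @param path File path.
#' @return `read_ledger()` returns a `flux_ledger`; `write_ledger()` returns
#'   `path` invisibly.
#' @export
write_ledger <- function(ledger, path) {
  out <- ledger
  names(out)[names(out) == "value"] <- "value_mg_co2e_per_yr"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  names(df)[names(df) == "value_mg_co2e_per_yr"] <- "value"
  class(df) <- c("flux_ledger", class(df))
  df
}

#' Write a report CSV with a commented YAML metadata header
#'
#' The header (lines starting `# `, delimited by `# ---`) records rounding,
#' units and provenance so a report is self-describing.
#'
#' @param df Data frame to write.
#' @param path File path.
#' @param metadata Named list written as YAML into the header.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(df, path, metadata = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(metadata)) {
    writeLines(c("# ---",
                 paste0("# ", strsplit(yaml::as.yaml(metadata), "\n")[[1]]),
                 "# ---"), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
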