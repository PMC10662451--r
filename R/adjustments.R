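# The five managed-land / forest-category adjustment configurations.
#
# Each spec is declarative: a complete include/exclude table over
# (IPCC category, forest type, component class), cell-level mask gates for
# each component, and three flags for the category refinements that need
# cell-level change information (undisturbed plantations). The engine's
# per-cell flux table is filtered by the spec; the complement (everything the
# spec excluded) is a first-class output so that adjusted + complement
# recovers the unadjusted ledger exactly.

.component_class <- function(component) {
  ifelse(component == "removal", "removal", "emission")
}

# full include/exclude grid, default include, with exceptions
.make_rules <- function(exclude = NULL) {
  g <- expand.grid(category = ipcc_categories(),
                   forest_type = forest_type_levels(),
                   component_class = c("emission", "removal"),
                   stringsAsFactors = FALSE)
  g$include <- TRUE
  if (!is.null(exclude)) {
    for (ex in exclude) {
      hit <- rep(TRUE, nrow(g))
      if (!is.null(ex$category)) hit <- hit & g$category %in% ex$category
      if (!is.null(ex$forest_type)) hit <- hit & g$forest_type %in% ex$forest_type
      if (!is.null(ex$component_class)) {
        hit <- hit & g$component_class %in% ex$component_class
      }
      g$include[hit] <- FALSE
    }
  }
  tibble::as_tibble(g)
}

#' Construct an adjustment specification
#'
#' @param name Spec identifier.
#' @param rules Tibble over (`category`, `forest_type`, `component_class`,
#'   `include`) covering every triple the engine can emit.
#' @param emission_mask,removal_mask Cell-level gate per component: one of
#'   `"none"`, `"managed_land"`, `"managed_forest"`.
#' @param extra_exclusions Named logical flags:
#'   `old_secondary_flfl_removals`, `undisturbed_plantation_removals`,
#'   `tree_crop_removals`.
#' @return An `adjustment_spec` object.
#' @export
adjustment_spec <- function(name, rules = .make_rules(),
                            emission_mask = "none", removal_mask = "none",
                            extra_exclusions = c(
                              old_secondary_flfl_removals = FALSE,
                              undisturbed_plantation_removals = FALSE,
                              tree_crop_removals = FALSE)) {
  stopifnot(emission_mask %in% c("none", "managed_land", "managed_forest"),
            removal_mask %in% c("none", "managed_land", "managed_forest"))
  full <- .make_rules()
  key <- paste(rules$category, rules$forest_type, rules$component_class)
  if (!setequal(key, paste(full$category, full$forest_type,
                           full$component_class)) || anyDuplicated(key)) {
    stop("configuration error: rules must cover every (category, type, component) once",
         call. = FALSE)
  }
  masks <- unique(c(emission_mask, removal_mask))
  structure(list(name = name, rules = rules,
                 emission_mask = emission_mask, removal_mask = removal_mask,
                 extra_exclusions = extra_exclusions,
                 mask_requirements = setdiff(masks, "none")),
            class = "adjustment_spec")
}

#' The built-in adjustment ladder
#'
#' Five configurations aligning earth-observation gain-loss accounting with
#' inventory conventions:
#' * `no_adjustment` - every flux inside the territorial boundary.
#' * `adjustment_1` - removals in primary forest excluded (primary extent as
#'   a proxy for unmanaged land); emissions kept country-wide.
#' * `adjustment_2a` - emissions and removals restricted to managed land.
#' * `adjustment_2b` - emissions on all managed land, removals only in
#'   managed forest, and removals in forest-converted-to-other-land excluded.
#' * `adjustment_2c` - as 2b, additionally excluding removals in old
#'   secondary forest remaining forest, in plantations that saw no loss
#'   ("plantations remaining plantations") and in tree crops, and the
#'   corresponding secondary/plantation forest-remaining-forest and
#'   tree-crop emissions.
#'
#' @return Named list of five [adjustment_spec] objects.
#' @export
builtin_specs <- function() {
  list(
    no_adjustment = adjustment_spec("no_adjustment"),
    adjustment_1 = adjustment_spec(
      "adjustment_1",
      rules = .make_rules(list(list(forest_type = "primary_old_growth",
                                    component_class = "removal")))),
    adjustment_2a = adjustment_spec(
      "adjustment_2a",
      emission_mask = "managed_land", removal_mask = "managed_land"),
    adjustment_2b = adjustment_spec(
      "adjustment_2b",
      rules = .make_rules(list(list(category = "FL_OL",
                                    component_class = "removal"))),
      emission_mask = "managed_land", removal_mask = "managed_forest"),
    adjustment_2c = adjustment_spec(
      "adjustment_2c",
      rules = .make_rules(list(
        list(category = "FL_OL", component_class = "removal"),
        list(category = "FL_FL",
             forest_type = c("old_secondary", "young_secondary",
                             "plantation_forest"),
             component_class = "emission"),
        list(forest_type = "tree_crop"))),
      emission_mask = "managed_land", removal_mask = "managed_forest",
      extra_exclusions = c(old_secondary_flfl_removals = TRUE,
                           undisturbed_plantation_removals = TRUE,
                           tree_crop_removals = TRUE)))
}

# per-row inclusion decision for a cell-flux table
.spec_includes <- function(spec, cf, stack) {
  cc <- .component_class(cf$component)
  key <- paste(cf$category, cf$forest_type, cc)
  rk <- paste(spec$rules$category, spec$rules$forest_type,
              spec$rules$component_class)
  inc <- spec$rules$include[match(key, rk)]

  gate <- function(mask_name) {
    if (mask_name == "none") return(rep(TRUE, nrow(cf)))
    layer <- stack[[mask_name]]
    if (is.null(layer)) {
      stop(sprintf("configuration error: adjustment '%s' requires the %s layer",
                   spec$name, mask_name), call. = FALSE)
    }
    as.vector(layer)[cf$cell]
  }
  inc <- inc & ifelse(cc == "removal", gate(spec$removal_mask),
                      gate(spec$emission_mask))

  ex <- spec$extra_exclusions
  rm_ <- cc == "removal"
  if (isTRUE(ex[["old_secondary_flfl_removals"]])) {
    inc <- inc & !(rm_ & cf$forest_type == "old_secondary" &
                     cf$category == "FL_FL")
  }
  if (isTRUE(ex[["undisturbed_plantation_removals"]])) {
    inc <- inc & !(rm_ & cf$forest_type == "plantation_forest" &
                     cf$category == "FL_FL")
  }
  if (isTRUE(ex[["tree_crop_removals"]])) {
    inc <- inc & !(rm_ & cf$forest_type == "tree_crop")
  }
  inc
}

#' Apply an adjustment specification to a stack
#'
#' Recomputes the per-cell gain-loss fluxes and keeps only the rows the spec
#' includes; every excluded (category, type, component) contributes exactly
#' zero. The ledger of excluded rows (the complement) is attached as the
#' `"complement"` attribute, so adjusted plus complement recovers the
#' unadjusted ledger.
#'
#' @param stack A [grid_stack] providing all layers in
#'   `spec$mask_requirements`.
#' @param factors A [factor_table].
#' @param spec An [adjustment_spec] (or a built-in name such as
#'   `"adjustment_2b"`).
#' @param options A [gainloss_options] list.
#' @return A `flux_ledger` with `provenance = spec$name` and a `"complement"`
#'   attribute holding the excluded-flux ledger.
#' @seealso [complement_ledger()]
#' @export
apply_adjustment <- function(stack, factors, spec,
                             options = gainloss_options()) {
  if (is.character(spec)) {
    specs <- builtin_specs()
    if (!spec %in% names(specs)) {
      stop(sprintf("configuration error: unknown adjustment '%s'", spec),
           call. = FALSE)
    }
    spec <- specs[[spec]]
  }
  for (m in spec$mask_requirements) {
    if (is.null(stack[[m]])) {
      stop(sprintf("configuration error: adjustment '%s' requires the %s layer",
                   spec$name, m), call. = FALSE)
    }
  }
  cf <- cell_fluxes(stack, factors, options)
  inc <- if (nrow(cf)) .spec_includes(spec, cf, stack) else logical(0)
  keep <- cf[inc, setdiff(names(cf), "cell")]
  drop <- cf[!inc, setdiff(names(cf), "cell")]
  led <- .aggregate_ledger(keep, stack$period, spec$name)
  attr(led, "complement") <- .aggregate_ledger(
    drop, stack$period, paste0(spec$name, "_complement"))
  led
}

#' @rdname apply_adjustment
#' @param ledger A ledger returned by [apply_adjustment()].
#' @export
complement_ledger <- function(ledger) attr(ledger, "complement")

#' Serialize adjustment specs to/from YAML
#'
#' @param spec An [adjustment_spec].
#' @param path File path.
#' @return `read_adjustment_spec()` returns an [adjustment_spec];
#'   `write_adjustment_spec()` returns `path` invisibly.
#' @export
write_adjustment_spec <- function(spec, path) {
  obj <- list(name = spec$name,
              emission_mask = spec$emission_mask,
              removal_mask = spec$removal_mask,
              extra_exclusions = as.list(spec$extra_exclusions),
              excluded = apply(spec$rules[!spec$rules$include, 1:3], 1,
                               paste, collapse = "|"))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_adjustment_spec
#' @export
read_adjustment_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  rules <- .make_rules()
  if (length(obj$excluded)) {
    parts <- do.call(rbind, strsplit(unlist(obj$excluded), "|", fixed = TRUE))
    key <- paste(rules$category, rules$forest_type, rules$component_class)
    rules$include[key %in% paste(parts[, 1], parts[, 2], parts[, 3])] <- FALSE
  }
  adjustment_spec(obj$name, rules = rules,
                  emission_mask = obj$emission_mask,
                  removal_mask = obj$removal_mask,
                  extra_exclusions = unlist(obj$extra_exclusions))
}

#' @export
print.adjustment_spec <- function(x, ...) {
  cat(sprintf("<adjustment_spec> %s | emissions: %s | removals: %s | %d excluded triples\n",
              x$name, x$emission_mask, x$removal_mask, sum(!x$rules$include)))
  flags <- names(which(x$extra_exclusions))
  if (length(flags)) cat("  extra exclusions:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}
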