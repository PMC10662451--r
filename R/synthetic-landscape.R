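# Seeded synthetic landscapes.
#
# The class map is built by multi-source region growing under exact per-class
# cell quotas: every class receives round(N * proportion) cells (quotas sum to
# N exactly), arranged as contiguous patches grown from seeded cells. Realized
# class fractions therefore match the configured proportions up to integer
# rounding while keeping the spatial coherence that mask-overlap statistics
# require. All randomness flows from a single integer seed through
# deterministic per-layer sub-streams.

# per-layer sub-stream seed (kept below 2^31)
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6 * 1009 + k * 7919) %% 2147483647)
}

# sample() without the length-1 surprise
.resample <- function(x, size) x[sample.int(length(x), size)]

# linear-index 4-neighbourhood on an H x W grid (column-major)
.neighbors <- function(idx, h, w) {
  r <- (idx - 1L) %% h + 1L
  cl <- (idx - 1L) %/% h + 1L
  c(idx[r > 1L] - 1L, idx[r < h] + 1L, idx[cl > 1L] - h, idx[cl < w] + h)
}

# exact integer quotas: floor + largest remainders (deterministic tie-break)
.class_quotas <- function(n, proportions) {
  q <- floor(n * proportions)
  frac <- n * proportions - q
  short <- n - sum(q)
  if (short > 0) {
    bump <- order(-frac, seq_along(frac))[seq_len(short)]
    q[bump] <- q[bump] + 1
  }
  stats::setNames(as.integer(q), names(proportions))
}

# grow contiguous class patches until every quota is met
.grow_class_map <- function(h, w, quotas, patch_target) {
  n <- h * w
  cls <- integer(n)
  remaining <- quotas
  classes <- which(quotas > 0L)
  for (k in classes) {
    n_seeds <- max(1L, min(remaining[k], as.integer(round(quotas[k] / patch_target))))
    free <- which(cls == 0L)
    seeds <- .resample(free, min(n_seeds, length(free)))
    cls[seeds] <- k
    remaining[k] <- remaining[k] - length(seeds)
  }
  guard <- 0L
  while (any(cls == 0L)) {
    guard <- guard + 1L
    if (guard > n + 100L) stop("internal error: region growing did not converge")
    progressed <- FALSE
    for (k in .resample(classes, length(classes))) {
      if (remaining[k] == 0L) next
      region <- which(cls == k)
      frontier <- unique(.neighbors(region, h, w))
      frontier <- frontier[cls[frontier] == 0L]
      if (!length(frontier)) {
        free <- which(cls == 0L)
        if (!length(free)) break
        seed <- .resample(free, 1L)
        cls[seed] <- k
        remaining[k] <- remaining[k] - 1L
        progressed <- TRUE
        next
      }
      take <- if (length(frontier) <= remaining[k]) frontier else
        .resample(frontier, remaining[k])
      cls[take] <- k
      remaining[k] <- remaining[k] - length(take)
      progressed <- TRUE
    }
    if (!progressed && any(remaining > 0L)) {
      stop("internal error: region growing stalled")
    }
  }
  matrix(cls, h, w)
}

# contiguous block of `target` cells grown inside `eligible` (linear indices)
.grow_block <- function(eligible, target, h, w) {
  if (target <= 0L || !length(eligible)) return(integer(0))
  in_set <- logical(h * w)
  in_set[eligible] <- TRUE
  block <- logical(h * w)
  start <- .resample(eligible, 1L)
  block[start] <- TRUE
  size <- 1L
  frontier <- start
  while (size < target) {
    nb <- unique(.neighbors(frontier, h, w))
    nb <- nb[in_set[nb] & !block[nb]]
    if (!length(nb)) break  # eligible component exhausted: keep block contiguous
    if (size + length(nb) > target) nb <- .resample(nb, target - size)
    block[nb] <- TRUE
    size <- size + length(nb)
    frontier <- nb
  }
  which(block)
}

#' Generate a seeded synthetic landscape
#'
#' Builds a [grid_stack] from a [landscape_config]: a contiguous-patch forest
#' type map with exact per-class cell quotas, per-class lognormal AGC,
#' geometric-waiting-time loss years, a forest-gain flag on nonforest cells,
#' one contiguous unmanaged block inside primary forest (the managed-land
#' mask is its complement), a confused second classification layer, the
#' managed-forest mask implied by that second classification, vertical biome
#' bands and a bottom-of-grid peat belt. Identical configs (including seed)
#' yield bit-identical stacks.
#'
#' @param config A [landscape_config].
#' @return A [grid_stack].
#' @examples
#' stack <- generate_landscape(landscape_config(32, seed = 7))
#' stack
#' @export
generate_landscape <- function(config) {
  cfg <- validate_landscape_config(config)
  h <- cfg$grid_height; w <- cfg$grid_width; n <- h * w
  lv <- forest_type_levels()

  set.seed(.sub_seed(cfg$seed, 1L))
  quotas <- .class_quotas(n, cfg$class_proportions)
  cls <- .grow_class_map(h, w, quotas, cfg$patch_target)
  ft <- matrix(lv[cls], h, w)

  set.seed(.sub_seed(cfg$seed, 2L))
  agc <- matrix(0, h, w)
  for (k in seq_along(lv)) {
    idx <- which(cls == k)
    if (!length(idx)) next
    d <- cfg$agc_distributions[[lv[k]]]
    agc[idx] <- if (d$family == "constant") d$value else
      stats::rlnorm(length(idx), d$meanlog, d$sdlog)
  }
  agc[cls == match("nonforest", lv)] <- 0

  set.seed(.sub_seed(cfg$seed, 3L))
  nyears <- period_length(cfg$period)
  loss <- matrix(NA_integer_, h, w)
  for (k in seq_along(lv)) {
    p <- cfg$annual_loss_prob[[lv[k]]]
    if (p <= 0) next
    idx <- which(cls == k)
    if (!length(idx)) next
    wait <- stats::rgeom(length(idx), p)  # whole years survived before loss
    yr <- cfg$period[1] + 1L + wait
    yr[yr > cfg$period[2]] <- NA_integer_
    loss[idx] <- yr
  }

  set.seed(.sub_seed(cfg$seed, 4L))
  gain <- matrix(FALSE, h, w)
  nf_idx <- which(cls == match("nonforest", lv))
  if (length(nf_idx) && cfg$gain_prob > 0) {
    gain[nf_idx] <- stats::runif(length(nf_idx)) < cfg$gain_prob
  }

  set.seed(.sub_seed(cfg$seed, 5L))
  primary_idx <- which(cls == match("primary_old_growth", lv))
  target <- as.integer(round(cfg$unmanaged_block_fraction * length(primary_idx)))
  block <- .grow_block(primary_idx, target, h, w)
  managed_land <- matrix(TRUE, h, w)
  managed_land[block] <- FALSE

  set.seed(.sub_seed(cfg$seed, 6L))
  alt <- cls
  for (k in seq_along(lv)) {
    rate <- cfg$confusion_rates[[lv[k]]]
    if (rate <= 0) next
    idx <- which(cls == k)
    if (!length(idx)) next
    hit <- idx[stats::runif(length(idx)) < rate]
    if (!length(hit)) next
    others <- setdiff(seq_along(lv), k)
    pr <- cfg$class_proportions[others]
    alt[hit] <- sample(others, length(hit), replace = TRUE, prob = pr / sum(pr))
  }
  alt_class <- matrix(lv[alt], h, w)

  # inventory-style managed forest: managed land that the second
  # classification maps to a forest class (tree crops count as cropland)
  inv_forest <- matrix(alt_class %in% c("primary_old_growth", "old_secondary",
                                        "young_secondary", "plantation_forest"),
                       h, w)
  managed_forest <- managed_land & inv_forest

  biome <- matrix(rep(pmin(cfg$biome_count,
                           1L + as.integer(floor((seq_len(w) - 1L) *
                                                 cfg$biome_count / w))),
                      each = h), h, w)

  peat <- matrix(FALSE, h, w)
  k_rows <- as.integer(round(h * cfg$peat_fraction))
  if (k_rows > 0) peat[(h - k_rows + 1L):h, ] <- TRUE

  grid_stack(forest_type_t0 = ft, agc_t0 = agc, loss_year = loss,
             gain_flag = gain, managed_land = managed_land,
             managed_forest = managed_forest, alt_class = alt_class,
             biome = biome, peat = peat, burn = NULL,
             cell_area = cfg$cell_area, period = cfg$period)
}
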