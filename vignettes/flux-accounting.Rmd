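---
title: "Gain-loss forest flux accounting and inventory reconciliation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gain-loss forest flux accounting and inventory reconciliation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxgap)
```

## The problem

Earth-observation (EO) products estimate forest greenhouse-gas fluxes
wall-to-wall, for every pixel inside a country's boundary. National
greenhouse-gas inventories (NGHGIs) estimate fluxes only on land the country
declares *managed* (the IPCC managed-land proxy), only in the forest
categories the inventory carries, and often over a different reporting
period. Naively comparing the two can flip the apparent sign of a country's
forest flux. `fluxgap` implements the machinery needed to make such
comparisons honestly: a per-pixel IPCC gain-loss engine, a ladder of
adjustments that progressively impose inventory conventions on the EO
accounting, temporal harmonization, and the comparison statistics used to
diagnose what drives a remaining gap (removal factors, forest-type
classification, managed-land extent, carbon-density distributions).

## The accounting model

Each grid cell carries a forest type at the period start, an aboveground
carbon density (AGC, Mg C/ha), an optional stand-replacing loss year, and a
gain flag. The cell-period maps to one IPCC transition category: forest
remaining forest (FL→FL), forest converted to other land (FL→OL), other land
converted to forest (OL→FL), plus the cropland-convention categories for
tree crops (CL→CL, OL→CL). Nonforest cells without gain fall outside the
accounting boundary and contribute nothing.

Two per-pixel operations generate the fluxes:

* **Committed emission** on loss, expanded from AGC to the major carbon
  pools with fixed ratios and converted stoichiometrically:
  $E = A\,\big[\mathrm{AGC}\,(1 + r_{rs} + r_{dw} + r_{lit}) +
  S\,\mathbb{1}_{soil}\big]\,\tfrac{44}{12}$,
  where $A$ is cell area (ha), $r_{rs}$ the root-to-shoot ratio, $r_{dw}$
  and $r_{lit}$ the dead-wood and litter ratios of AGC, and $S$ an optional
  committed soil term (Mg C/ha). Emissions are annualized by dividing by the
  period length, so every ledger entry is an average-annual flux.
* **Removal flux** per stratum:
  $R = -A\,\mathrm{RF}(b, t)\,\tfrac{44}{12}\,\tfrac{y}{n}$,
  where $\mathrm{RF}$ is the removal factor (Mg C/ha/yr) of biome $b$ and
  forest type $t$, $n$ the period length in years, and $y$ the years the
  cell was forested: $n$ without loss, $y_{loss} - y_{start}$ with loss
  (accrual up to, exclusive of, the loss year). Whether lost cells accrue
  any removals at all is configurable (`removals_on_loss_cells`), since
  EO-internal conventions differ and inventories typically book no uptake on
  converted land.

Optional components book peat decomposition after loss on peat soils
(Mg CO2e/ha/yr from the loss year to the period end), peat fires and
biomass burning in forest remaining forest (per-event factors on
burn-flagged cells). Peat fires are booked only for cells inside the
accounting boundary: a fire on nonforest land that saw no forest transition
is not a forest-related flux. Soil and peat terms default off, matching a
Brazil-style CO2-only comparison; an Indonesia/Malaysia-style run turns
them on.

Cells gained during the period (OL→FL from nonforest) are booked under the
young-secondary stratum — by construction they are regrowth younger than 20
years — with a configurable accrual fraction (default 0.5, i.e. mid-period
establishment on average). This is a deliberate simplification: the stack
records *that* a cell gained forest, not *when*.

The ledger is the grouped sum of per-cell values by (region = biome, IPCC
category, forest type, component). R accumulates sums in extended precision,
which keeps the additivity and complement identities below well inside 1e-9
relative error. Removal rows are never positive, emission rows never
negative, and the net flux is their algebraic sum.

## The adjustment ladder

Five declarative configurations reproduce the include/exclude semantics used
when aligning EO accounting with an inventory:

| name | emissions | removals |
|---|---|---|
| `no_adjustment` | whole boundary | whole boundary |
| `adjustment_1` | whole boundary | excluded in primary forest |
| `adjustment_2a` | managed land | managed land |
| `adjustment_2b` | managed land | managed forest, FL→OL excluded |
| `adjustment_2c` | as 2b, minus secondary/plantation FL→FL and tree-crop emissions | as 2b, minus old-secondary FL→FL, undisturbed plantations, tree crops |

Each spec is an explicit include/exclude table over (category, type,
component class) plus cell-level mask gates, so the removal cell-set shrinks
monotonically along `no_adjustment` → 2a → 2b → 2c (adjustment 1 is a
branch compared only against no adjustment). Design choices worth
recording:

* "Plantations remaining plantations" is operationalized as plantation
  cells with no loss in the period, i.e. plantation FL→FL.
* Old secondary forest (regrowth older than 20 years) represents "secondary
  forest remaining secondary forest"; *young*-secondary FL→FL removals stay
  included under 2c. The underlying tick/cross table is coarser than the
  procedure's prose here; we follow the refined reading and additionally
  drop the (normally burn-only, hence usually zero) FL→FL emissions of the
  secondary and plantation rows to match the table.
* Tree-crop exclusion under 2c keys on the forest-type code, independent of
  the cropland-convention flag, because both inventory conventions place
  tree crops in cropland.
* Under 2b, fluxes of non-managed old-growth are excluded on both
  components via the managed-land emission gate; the source table leaves
  the emission mark blank on that row, and exclude-both is the reading
  consistent with 2a and 2c.
* The managed-forest mask is a single snapshot layer; no mask dynamics.

`apply_adjustment()` always returns the complement ledger (the excluded
rows) as an attribute, which makes the exclusion-completeness identity —
adjusted + complement = unadjusted, exactly — directly testable.

## Temporal harmonization

Estimates reported over different periods are aligned by fractional
rescaling against a reference annual series:
`x * mean(ref over target period) / mean(ref over short period)`, with
arithmetic means over calendar years, both endpoints inclusive. Rescaling is
applied separately to gross emissions and gross removals (and per region);
the net flux is recomputed afterwards, never rescaled directly, because the
mean-ratio of a difference is not the difference of mean-ratios. The
operation is linear, is the identity on equal periods, and composes
(A→B then B→C equals A→C). Short inventory series are carried forward by
repeating the last reported year (`extend_last_year()`, idempotent).

## Comparison statistics

* `modal_factor()` — the most frequent factor value in a stratum, ties to
  the smallest value; summarises which removal factor a gridded dataset
  effectively applies inside an inventory biome.
* `pct_difference()` — `100 (candidate − reference)/reference`, rounded
  half-away-from-zero to the decimals of the printed report (integer for
  old-growth and young-secondary comparisons, one decimal for plantations;
  the convention is pinned by a reference cell that sits exactly on a .5
  tie). Satisfies `(1+p_ab/100)(1+p_ba/100)=1` before rounding.
* `cross_tabulate()` — row-normalized classification-agreement matrix
  between two forest-type layers; zero-count rows are flagged rather than
  silently normalized.
* `overlap_percent()` — `100 |a ∧ b| / |b|`; the *second* mask is the
  denominator, callers choose orientation.
* `area_table()`, `swamp_dry_ratio()`, `removals_by_type_report()` — areas
  in thousand hectares (count × cell area), ratios reported at two
  decimals, report totals summed before rounding.
* `agc_summary()` / `iqr_overlap()` — mean and type-7 quartiles of AGC in a
  stratum (the quantile convention is not prescribed by inventory practice;
  type 7 is R's default and is stated in the report metadata), and the
  interquartile-interval intersection test.

Packaged reference tables (`ref_*()`) transcribe the published
factor, area and removal comparisons for Brazil, Indonesia and Malaysia
that the worked examples recompute. One transcription note: the Malaysian
EO old-growth area is stored as 12,483.4 kha, the value implied by the
printed forest-land subtotal (17,079.3 − 4,595.9); the source table prints
it with a shifted digit separator.

## The synthetic landscape generator

No gridded inputs ship with inventories, so the generator builds the
landscapes the pipeline assumes, emulating a tropical country:

* **Class map**: every class receives an exact cell quota
  (`round(N × proportion)`, largest-remainder rounding) arranged as
  contiguous patches by seeded multi-source region growing
  (`patch_target` cells per patch, default 64). Exact quotas mean realized
  fractions match configured proportions up to a cell, while patches give
  the spatial coherence that mask-overlap statistics need. Patch size is a
  free choice — there is no empirical characterization of the spatial
  autocorrelation of dataset disagreement to calibrate against — and is
  exposed in the config.
* **AGC**: per-class lognormal (constant for nonforest), defaults with the
  old-growth median highest (150 Mg C/ha), old secondary 90, plantations
  55, tree crops 40, young secondary 30, matching the skewed, ordered
  distributions typical of tropical carbon maps.
* **Loss**: per-cell geometric waiting time with per-class annual
  probability; the first success inside the period sets the loss year.
  Defaults (0.4-2%/yr, highest in plantations) keep the 20-year landscape
  majority-forested.
* **Unmanaged block**: a contiguous block grown inside primary forest
  covering `unmanaged_block_fraction` of primary cells (default 0.5, an
  Amazon-like large protected/unmanaged interior); managed land is its
  complement.
* **Second classification**: each cell relabels with a per-class confusion
  probability; the new label is drawn from the other classes proportionally
  to their landscape shares. The default relabels 65% of old-secondary
  cells — mostly into old-growth, the dominant class — emulating an
  inventory that maps EO secondary forest as managed old-growth. The
  managed-forest mask is managed land whose *second* classification is a
  forest class, which is exactly how an inventory mask disagrees with an
  EO-derived forest extent.
* **Biomes** are vertical bands; **peat** is a bottom-of-grid belt of rows.

A single integer seed drives everything through fixed per-layer sub-streams,
so identical configs give bit-identical stacks. What the generator does
*not* emulate: real geometry of any country's biomes, Landsat radiometry,
sub-pixel degradation, or temporally varying management. Passing tests
therefore demonstrate correctness of the accounting and statistics on
structurally realistic inputs, not agreement with any real national dataset.

## Numerical and I/O choices

* Grids are row-major, origin top-left; categorical nodata is 255 on disk,
  the loss-year band uses 0 as the no-loss sentinel with a 1900 offset.
* Layers serialize as single-band TIFFs (8/16-bit scaled integers for
  categorical bands — bit-exact round-trip; 32-bit float for AGC with a
  power-of-two scale recorded in the YAML sidecar — round-trip within
  float32 relative precision, ~1e-6).
* CSV everywhere: UTF-8, comma-separated, `.` decimal, mandatory header;
  reports carry a commented YAML metadata block (units, rounding,
  provenance); YAML for configs.
* Degenerate inputs fail loudly with named errors: mismatched layer
  dimensions, loss on nonforest, empty strata, zero reference means,
  unresolvable (biome, type) strata, missing mask layers (named).

## Problem sizes used by the checks

The verification suite runs the engine against an independent per-cell loop
oracle on random 16-32 cell-square stacks (1e-9 relative tolerance), the
adjustment ladder and complement identities over 20 seeded 24×24
landscapes, confusion-rate recovery on a 100×100 (10^4-cell) landscape
within three binomial standard errors, and full-pipeline determinism at
32×32; the acceptance script uses a 96×96 landscape. These sizes give every
stratum and component non-trivial mass while keeping a full run in seconds;
all scale linearly in cell count if larger landscapes are wanted.

## Worked example

```{r example}
factors <- tropical_default_factors()
stack <- generate_landscape(landscape_config(64, seed = 7))
ledgers <- lapply(builtin_specs(), function(s) apply_adjustment(stack, factors, s))
sapply(ledgers, function(l) c(net = net_flux(l),
                              E = gross_emissions(l),
                              R = gross_removals(l)))
```

The removal magnitude shrinks along the ladder while emissions only drop
where the managed-land gate bites — the same mechanism by which a
countrywide EO net sink can become an inventory-comparable net source.

## Known limitations

Degradation (sub-pixel carbon loss) is not modeled; removal factors are
applied per stratum rather than per-pixel age curves; the harmonization
module implements the mean-ratio formula, not the specific national fraction
tables of any inventory; and no statistical significance test is offered for
dataset differences — with flux uncertainties of 30-110%, interval-overlap
tests are uninformative, and the package instead quantifies the mechanisms
behind a gap.
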