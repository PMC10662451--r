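# fluxgap

Reconciling forest carbon flux estimates from earth observation with
national greenhouse-gas inventories.

## The problem

Wall-to-wall earth-observation (EO) flux products and national greenhouse-gas
inventories (NGHGIs) can disagree on a country's forest carbon flux by more
than the flux itself — even on its sign. Most of the gap is definitional:
inventories report only on *managed* land (the IPCC managed-land proxy),
only for the forest categories they carry, with their own removal factors,
forest-type maps and reporting periods. `fluxgap` provides the machinery to
quantify and close that gap, for analysts doing inventory
measurement/reporting/verification (MRV) work and for anyone comparing
gridded flux products against tabular national reporting.

## What it implements

* **IPCC gain-loss engine** (`run_gain_loss()`): per-pixel accounting over
  aligned raster layers. Committed emissions on stand-replacing loss expand
  aboveground carbon (AGC) to the major pools,
  `E = A [AGC (1 + r_rs + r_dw + r_lit) + S·1_soil] · 44/12`, annualized
  over the period; removals apply per-stratum factors,
  `R = −A · RF(biome, type) · 44/12 · years_forested / period_length`,
  with accrual up to the loss year. Optional peat decomposition, peat-fire
  and forest-remaining-forest burning components. Results are
  component-labelled ledgers by region × IPCC category × forest type.
* **Adjustment ladder** (`builtin_specs()`, `apply_adjustment()`): five
  declarative include/exclude configurations — no adjustment; primary-forest
  removal exclusion; managed-land masking; managed-forest removal masking
  with forest-conversion removal exclusion; and the full inventory
  convention additionally dropping old-secondary remaining-forest,
  undisturbed-plantation and tree-crop fluxes. Complement ledgers make the
  exclusions exactly auditable.
* **Temporal harmonization** (`fractional_rescale()`,
  `extend_last_year()`): mean-ratio rescaling of period-average fluxes
  against a reference annual series, and last-year extension of short
  series.
* **Comparison statistics** (`modal_factor()`, `pct_difference()`,
  `cross_tabulate()`, `overlap_percent()`, `area_table()`,
  `swamp_dry_ratio()`, `agc_summary()`, `removals_by_type_report()`), plus
  packaged reference tables (`ref_*()`) transcribing the published
  Brazil/Indonesia/Malaysia factor and area comparisons.
* **Synthetic landscape generator** (`generate_landscape()`): seeded
  tropical-country mosaics — contiguous patches with exact class quotas,
  lognormal AGC, geometric loss waiting times, a contiguous unmanaged
  primary block, and an inventory-style second classification with
  configurable confusion — standing in for the non-public gridded inputs.

## Worked example

```r
library(fluxgap)
factors <- tropical_default_factors()
stack   <- generate_landscape(landscape_config(64, seed = 7))
ledgers <- lapply(builtin_specs(), function(s) apply_adjustment(stack, factors, s))
round(sapply(ledgers, function(l)
  c(net = net_flux(l), E = gross_emissions(l), R = gross_removals(l))), 1)
#>     no_adjustment adjustment_1 adjustment_2a adjustment_2b adjustment_2c
#> net       -1369.7      -1061.9       -1409.4        -760.6         173.7
#> E           834.6        834.6         659.2         659.2         631.1
#> R         -2204.4      -1896.5       -2068.6       -1419.8        -457.4
```

All values are average-annual Mg CO2e/yr over 2001-2020. Reading the
columns: the whole landscape is a net sink (−1369.7); excluding removals in
primary forest (adjustment 1) or restricting removals to the inventory's
managed forest (2b) shrinks the sink; imposing the full inventory category
conventions (2c) flips the landscape to a net source (+173.7), with
emissions barely changed — exactly the definitional mechanism that separates
EO products from inventories. (2a's *net* sink is slightly deeper than the
unadjusted one because the managed-land gate trims more emissions than
removals on this landscape; the removal magnitude itself is monotone along
no adjustment → 2a → 2b → 2c.)

The comparison side works directly on the packaged reference tables:

```r
t5 <- ref_oldgrowth_factors()
pct_difference(t5$rf_eo_comparison, t5$rf_inventory)
#> [1]  23  34  20  20  34 850   # per biome, EO vs inventory old-growth RF, %
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/fluxgap.R`
(`Rscript fluxgap.R {simulate|account|adjust|harmonize|run} ...`).

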