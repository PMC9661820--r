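# hsrsquant

Single-cell chemical imaging analysis for hyperspectral stimulated Raman
scattering (hSRS) microscopy of product-accumulating bacteria.

Engineered *E. coli* producing the monoterpene limonene store it in
bright intracellular aggregates. hSRS records a Raman spectrum at every
pixel (a λ-x-y stack), and limonene's 760 cm⁻¹ fingerprint band makes
those aggregates chemically identifiable. `hsrsquant` implements the
full analysis chain for this kind of experiment, for microscopists and
metabolic engineers who want per-cell, per-aggregate numbers out of raw
stacks:

* **Spectral unmixing.** Per-pixel LASSO decomposition
  `ĉ = argmin ½‖d − cS‖₂² + λ‖c‖₁` of each pixel spectrum `d` into
  reference spectra `S` (limonene, cell body, background), solved by
  cyclic coordinate descent with exact soft-threshold updates,
  optionally nonnegative. Yields one concentration map per channel plus
  a residual map.
* **Segmentation.** Classical cell segmentation (smooth → Otsu →
  watershed split → size filter), top-hat aggregate detection inside
  cells, and an importer for externally corrected label masks.
* **Quantification.** Per-cell and per-aggregate feature tables (area,
  major axis, channel intensities, 760 cm⁻¹ peak, window sums); the
  polar-localization metric d/L (arc distance from the aggregate to the
  farther cell pole over the geodesic cell length, so d/L ∈ [0.5, 1]);
  threshold-sweep classification of analyte-rich aggregates against a
  control population; Wilcoxon rank-sum comparisons; calibration-line
  fitting with a 3σ/slope limit of detection.
* **Colocalization.** Mander's colocalization coefficient
  `MCC = Σᵢ Limᵢ·[LimSynᵢ ≥ θ] / Σᵢ Limᵢ` between the limonene map and
  an enzyme-fluorescence channel, restricted to intracellular pixels.
* **Synthetic scenes.** A ground-truthed generator of rod-shaped cells
  with polar aggregates, rendered through the exact forward model
  `D = CS + E`, so every stage is testable without instrument data.

## Worked example

```r
library(hsrsquant)
out <- tempfile()
manifest <- run_demo(out, seed = 1)
#> [hsrsquant] simulate: 40 cells, seed 1
#> [hsrsquant] unmix: lambda 0.05
#> [hsrsquant] segment
#> [hsrsquant] quantify: 40 cells, 10 aggregates
#> [hsrsquant] colocalize
#> [hsrsquant] done: 15 files in /tmp/...

s <- attr(manifest, "summaries")
s$frac_cells_with_aggregates
#> [1] 0.2
s$mcc
#> [1] 0.9645
```

The demo simulates a 360×360 px scene of 40 cells in which each cell
bears an aggregate with probability 0.19, unmixes the rendered 24-frame
fingerprint stack (670–900 cm⁻¹), segments cells and aggregates,
and reports — among other things — the fraction of aggregate-bearing
cells (0.2 here, the realized Bernoulli draw) and the Mander's
coefficient against the simulated enzyme-fluorescence channel (high,
because the generator colocalizes 85% of the fluorescence with the
aggregates by default). `out/` contains the concentration maps
(32-bit TIFF + scale sidecars), label masks (16-bit TIFF), feature
tables (CSV), summaries (JSON) and a checksummed `manifest.json`.

Individual stages are plain functions — `unmix_stack()`,
`segment_cells()`, `segment_aggregates()`, `extract_cell_features()`,
`mcc()`, `fit_calibration()` — and a thin CLI with `simulate`, `unmix`,
`segment`, `quantify`, `colocalize`, `run` and `demo` subcommands lives
at `inst/scripts/hsrsquant-cli.R`.

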