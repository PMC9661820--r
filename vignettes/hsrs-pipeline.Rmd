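---
title: "Methods: hyperspectral SRS unmixing and single-cell aggregate quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral SRS unmixing and single-cell aggregate quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsrsquant)
```

## The problem

Engineered *E. coli* strains that express a heterologous monoterpene
pathway can accumulate their product — here limonene — in dense
intracellular aggregates rather than spreading it through the cytoplasm.
Hyperspectral stimulated Raman scattering (hSRS) microscopy records a
Raman spectrum at every pixel (a "λ-x-y" stack), and limonene carries a
sharp, chemically specific band at 760 cm⁻¹ in the fingerprint region
(670–900 cm⁻¹) that neither proteins nor common lipids share. This
package turns such stacks into per-pixel chemical concentration maps,
segments individual cells and their aggregates, and quantifies where and
how much product each cell stores.

## The unmixing model

Each pixel's spectrum $d \in \mathbb{R}^{N_\lambda}$ is modelled as a
linear mixture of $k$ reference spectra stacked into
$S \in \mathbb{R}^{k \times N_\lambda}$ (limonene, cell body,
background), with coefficients $c \in \mathbb{R}^k$ estimated by the
L1-penalized least squares (LASSO) problem

$$\hat c = \arg\min_c \tfrac12 \lVert d - cS \rVert_2^2
          + \lambda \lVert c \rVert_1 .$$

The sparsity penalty encodes the biological premise that limonene is
confined to aggregates: most pixels genuinely contain no analyte, and the
penalty drives those coefficients to exactly zero instead of letting
noise leak into the limonene channel.

The solver is cyclic coordinate descent with exact per-coordinate
soft-threshold updates, warm-started at zero. Numerical choices that
matter:

* **Stopping.** A pixel is converged when, over one full cycle, its
  relative objective change falls below `tol` (default $10^{-8}$) *and*
  its relative coefficient change falls below $\sqrt{\texttt{tol}}$. The
  objective is quadratically flat near the optimum, so an
  objective-only rule can stop orders of magnitude short of coefficient
  convergence when references are correlated; the paired rule restores
  accuracy at negligible cost.
* **Independence.** Converged pixels are frozen individually, so a
  pixel's solution depends only on its own spectrum and unmixing
  commutes with spatial cropping — a property the test suite asserts.
* **Nonnegativity.** On by default: concentrations are physical. Each
  coordinate update is clipped at zero, which is the exact coordinate
  minimizer of the constrained problem. A flag restores the
  unconstrained LASSO.
* **Reference normalization.** References are max-normalized before
  fitting by default, so channel units are "fraction of pure-reference
  peak intensity". Raw-unit fitting is available
  (`normalize_refs = "none"`).
* **Choosing λ.** The data do not dictate λ; `choose_lambda()` selects
  the largest candidate whose mean residual over non-cell pixels stays
  within 1.1× the unpenalized residual, the idea being that the penalty
  should cost nothing where nothing but background is present. One λ is
  then held fixed for all stacks from one acquisition condition. The
  package default (λ = 0.05 on max-normalized references) corresponds to
  roughly the noise-level correlation `s·ε` at the default noise
  (σ = 0.02 over 24 frames).
* **Background reference.** Estimated per stack as the mean spectrum of
  the non-cell area (Otsu on the spectrally summed image when no mask is
  given), mirroring how practitioners remove the solvent/substrate
  contribution.

## Segmentation

The original workflow used interactive pixel + object classification;
that is deliberately out of scope here. Instead `segment_cells()` runs a
deterministic classical pipeline (Gaussian smooth → Otsu → hole filling
→ optional watershed split on the distance transform → size filter), and
`import_labels()` loads externally produced, manually corrected masks so
the rest of the pipeline is indifferent to where masks come from.
Aggregates are found inside cells by a white top-hat (disc radius 4 px by
default, comfortably larger than the 2 px aggregate radius the simulator
uses) followed by a fixed threshold on the top-hat response (default
0.15, half the minimum simulated aggregate concentration), connected
components and a centroid-based parent assignment. Components are
8-connected throughout, and pixel indices are R's native 1-based
row/column convention everywhere.

## The d/L localization metric

For each aggregate-bearing cell the *central line* is computed as the
longest geodesic path through the cell's pixel set (8-connected graph,
√2 diagonal steps, two farthest-point sweeps followed by a shortest
path). Its endpoints are the cell poles and its arc length is the cell
length $L$. The aggregate position is projected onto this line — either
the line pixel nearest the aggregate centroid (default, `centroid`
mode) or the brightest line pixel in the limonene map (`maxline` mode) —
and $d$ is the arc distance to the *farther* pole, so $d/L \in [0.5, 1]$
by construction, with 1 meaning perfectly polar. We chose the geodesic
diameter over skeletonization-plus-pruning because it needs no pruning
heuristics, is exact for rod-shaped and moderately bent cells, and
degrades gracefully: for nearly round objects the two definitions
diverge, and `aggregate_location()` refuses cells whose geodesic length
is degenerate. Pixelation limits accuracy to about 1.5/L, which the
generator round-trip test enforces.

## Classifying limonene-rich aggregates

Aggregate intensities are only meaningful relative to a control strain,
so the classification threshold is swept: for each candidate threshold
the fraction of aggregates classified positive is computed in both the
pathway-bearing population and a control population (normalized so the
control cell-body mean equals 1, making the threshold a unitless ratio),
and the chosen threshold is the smallest grid value at which the control
false-positive fraction reaches a tolerance (default zero). The exact
selection rule behind published thresholds of this kind is rarely
stated; this rule is a declared design choice, and the full sweep curve
is returned so users can apply their own.

## Colocalization

Mander's colocalization coefficient restricted to intracellular pixels:

$$\mathrm{MCC} = \frac{\sum_i \mathrm{Lim}_i \,
  [\mathrm{LimSyn}_i \ge \theta]}{\sum_i \mathrm{Lim}_i}$$

with an inclusive comparison. The fluorescence threshold θ is Otsu's
within cells by default (quantile thresholds available); when comparing
conditions the threshold should be fixed across them, since MCC is
monotone in θ and a per-condition threshold confounds the comparison.
MCC is invariant to positive rescaling of either channel (with θ scaled
alongside the fluorescence), which the tests assert.

## Calibration and detection limit

A dilution series is fitted by ordinary least squares;
`blank_sigma` is the standard deviation of the concentration-zero
replicates and the limit of detection is the 3σ convention
$\mathrm{LOD} = 3\,\sigma_\mathrm{blank}/\mathrm{slope}$.
`estimate_concentration()` inverts the line, flooring at zero.
Concentration claims from SRS intensities are only as good as the
calibration transfer between solution standards and the intracellular
environment, which this package does not attempt to model.

## What the synthetic generator emulates — and what it does not

`generate_scene()` draws non-overlapping 2D spherocylinders (length
2–4 µm, width 0.8 µm, 0.1 µm/px — typical rod geometry at a
high-NA system's sampling) with a 2 px placement gap; a cell carries
aggregates with probability 0.19, with 1 or 2 of them (weights 0.8/0.2),
and each aggregate's axial position is drawn from a truncated normal on
d/L with mean 0.8 and sd 0.08, clipped to [0.5, 1] and to positions
where the 0.2 µm aggregate physically fits inside the cell. These
defaults encode the population structure the analysis is designed to
measure: a minority subpopulation of aggregate-bearing cells with a
strong polar bias peaking in the 70–90% stretch of the cell. Aggregate
limonene levels are uniform on [0.3, 1] in max-normalized reference
units (a broad spread mirroring strong cell-to-cell variation in
product content); the limonene coefficient is exactly zero outside
aggregates — the sparsity premise the LASSO relies on. Rendering is the
exact forward model $D = CS + E$ with additive Gaussian noise
(σ = 0.02 per pixel and frame; lock-in detected SRS noise is
approximately Gaussian, and a Poisson option exists), plus an optional
Gaussian PSF blur. The fluorescence channel places enzyme emission on
aggregates in proportion to their limonene content, relocates a
configurable fraction to random in-cell sites, and blurs it.

Passing tests on these scenes demonstrate correctness of the
*algorithms* under the stated statistical structure. They do not
demonstrate robustness to what real bacterial hSRS data add: spectral
baselines and instrument drift, out-of-focus light and 3D sectioning,
cell clumping and division septa, reference spectra measured with their
own noise, or aggregates below the diffraction limit. The importer for
external masks and the explicit reference-CSV path exist precisely so
the quantitative stages can be reused when those complications are
handled upstream.

## Problem sizes and determinism

The validation suite runs the solver oracles on 50 single-reference and
20 three-reference instances, the exact-inversion check on a
24×256×256 noiseless stack, and the full-pipeline recovery on a
24×1200×1200 stack with 500 cells — large enough for the binomial
3-standard-error band around the 0.19 bearing fraction (±0.053) and the
±0.03 band on mean d/L to be meaningful, while keeping a desk-scale
runtime. All randomness flows from explicit integer seeds; the demo
pipeline writes no timestamps into its artifacts, so two runs with one
seed produce byte-identical manifests, which is both asserted in the
tests and reported by the acceptance script.

## Known limitations

* Concentration maps are relative to the supplied references; absolute
  molarity requires the calibration route and shares its assumptions.
* The classical segmenter expects well-separated single-layer cells;
  dense colonies need externally corrected masks.
* λ selection assumes the non-cell area is analyte-free; scenes without
  background pixels need a user-supplied λ.
* The geodesic central line is undefined for round (non-rod) cells, and
  d/L loses meaning there.

## A worked example

```{r demo, eval = FALSE}
out <- tempfile()
manifest <- run_demo(out, seed = 1)
attr(manifest, "summaries")$frac_cells_with_aggregates
```
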