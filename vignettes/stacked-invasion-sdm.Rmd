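---
title: "Stacked ensemble SDMs for invasion risk: models, design choices, and what the synthetic benchmarks show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensemble SDMs for invasion risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis

`invstack` implements a stacked ensemble species-distribution-modelling
(SDM) pipeline of the kind used to map plant-invasion risk at
macroecological scale. Given presence-only occurrence records for a pool of
naturalized alien species and gridded environmental layers for a current
period and future scenarios, the pipeline:

1. filters records (spatial deduplication, environmental-space thinning,
   a minimum-record rule),
2. draws pseudo-absences outside a climatic surface range envelope,
   weighted by a sampling-effort field (target-group bias correction),
3. fits four model families (GLM, GAM, random forest, boosted trees) on
   two alternative predictor sets and scores them by spatial block
   cross-validation with the continuous Boyce index,
4. combines models with cross-validated Boyce index above 0.6 into a
   Boyce-weighted ensemble and binarizes its predictions at the
   Boyce-maximization threshold,
5. stacks the per-species binary maps into potential richness, and derives
   invasion hotspots, richness change, species turnover,
   coefficient-of-variation uncertainty, Whittaker-biome summaries and a
   continent-restricted dispersal sensitivity.

Because real pipelines of this kind are validated only indirectly, the
package ships a first-class synthetic-world generator
(`make_world()`, `make_species()`, `sample_occurrences()`): virtual species
with known Gaussian niches, sampled with realistic observation bias, so
that every stage can be tested against ground truth.

# Models and statistics

## Niche truth and occurrence model

Each virtual species has suitability
$S^*(x) = \prod_v \exp\{-(x_v - \mu_v)^2 / 2\sigma_v^2\}$
over a configured set of environmental layers, rescaled so
$\max S^* = 1$ over land. Occurrence records are drawn with replacement
with probability proportional to $S^* \times \text{effort}$, with
$N \sim \text{Poisson}(\lambda)$, plus a small fraction of
suitability-independent records (`error_rate`, default 2%) that emulates
the misidentified, cultivated or vagrant specimens surviving coordinate
cleaning in aggregator data. The product-Gaussian form admits closed-form
truth values for recovery tests.

## Continuous Boyce index

`boyce_index()` slides `n_windows = 101` overlapping suitability windows
of width `window_width = 0.1` across $[0,1]$; for window $i$, $P_i$ is the
share of presence predictions inside it, $E_i$ the share of background
predictions, and $F_i = P_i / E_i$. Windows with $E_i = 0$ are dropped;
the index is the Spearman correlation of $F_i$ with the window midpoints:
1 for perfect ranking, 0 for random, −1 for inverted. Being a rank
statistic it is invariant under strictly increasing transformations of the
prediction scale (asserted to $10^{-9}$ in the tests).

**Evaluation background.** Two backgrounds are implemented. The default
(`boyce_background = "calibration"`) scores held-out presences against the
held-out fold's calibration points (presences + pseudo-absences), the
convention of ensemble-SDM validation platforms: because the scored
presences are part of the background, $F$ is bounded (at
$\approx (n_\text{pres}+n_\text{PA})/n_\text{pres}$) and its upper plateau
is stable. The alternative (`"landscape"`) uses predictions at every land
cell — availability in the strict sense — but is much noisier at realistic
fold sizes (a few dozen presences): windows with near-zero expected
frequency produce wild $P/E$ excursions, and in our experiments even the
*true* suitability surface then frequently scores below the 0.6 retention
threshold. We therefore treat the calibration background as the default
and keep the landscape background available for sensitivity analyses.

## Model families

"Default settings" of the four families are interpreted as the
conventional defaults of ensemble-SDM practice:

* **GLM** — logistic regression over linear + quadratic terms per
  predictor with stepwise AIC selection from the null model. The quadratic
  terms allow unimodal responses; the selection step matters because
  presence/SRE-outside-pseudo-absence designs are nearly separable, and an
  unselected, unpenalized quadratic fit saturates at 0/1 and loses the
  rank information the Boyce index measures.
* **GAM** — binomial `mgcv` model with shrinkage thin-plate smooths
  (`bs = "ts"`, basis dimension 5) and REML smoothness selection.
* **RF** — `randomForest` classification with 500 trees.
* **BRT** — gradient boosting with the slow-learning recipe standard in
  distribution modelling: 150 rounds, learning rate 0.05, interaction
  depth 2, bag fraction 0.75, single thread, seeded.

All predictions are clamped to $[0,1]$; every stochastic fit is a pure
function of its seed.

## Cross-validation, ensembling, binarization

Calibration points are split into 2×2 spatial blocks at the median row and
column (`make_blocks()`; points on a median go to the lower-index block).
Each fold trains on three blocks and scores the fourth; the
cross-validated score is the mean over folds with a defined index. Models
with `cv_boyce > 0.6` (strict) enter the ensemble with weights
proportional to their scores; members never mix predictor sets. The
binarization threshold $t^*$ is the lowest Boyce-curve midpoint from which
$P/E \ge 1$ holds for all retained midpoints upwards (the stable crossing;
`method = "fmax"` — the midpoint of maximal $F$ — is the exposed
alternative). The same $t^*$ binarizes all five scenario projections of a
species × predictor set.

## Stacking and downstream analytics

Richness is the cellwise sum of binary maps per ensemble *member*
(predictor set for the current period; predictor set × realization for
futures); the consensus map is the member mean, and the
coefficient-of-variation raster (sample sd / mean, masked at mean 0) is
computed across members. Hotspots are cells with richness strictly above
$c = \lfloor f \cdot M \rfloor$ for modelled pool size $M$ and fraction
$f \in \{0.05, 0.10, 0.15\}$; future maps reuse the cut-off count
established under current conditions. Turnover is the per-cell Jaccard
dissimilarity between current and future suitable-species sets (0 =
unchanged list, 1 = no species shared; both-empty cells score 0), computed
per member and averaged; a gains+losses rate index is exposed as an
alternative since the two share both endpoints. Proportional change and CV
are masked — not zero, not infinite — where the denominator is 0.

## Biome space

Land cells are assigned to one of nine Whittaker biomes by
point-in-polygon tests in (mean annual temperature °C, annual
precipitation cm) space; points outside every polygon take the nearest
polygon in standardized coordinates, and boundary overlaps resolve to the
lowest biome id, so the assignment is total and deterministic. The
polygon fixture (`extdata/whittaker_biomes_synthetic.csv`) is a simplified
synthetic approximation of the classic diagram — adequate for biome
bookkeeping on synthetic worlds, not a digitization of any published
figure. Richness-weighted kernel density in the same space uses a
weighted product-Gaussian kernel with per-axis normal-reference plug-in
bandwidths ($h_j = \hat\sigma_j n_\text{eff}^{-1/6}$, effective sample
size $n_\text{eff} = (\sum w)^2/\sum w^2$), evaluated on a 256×256 grid;
the 95% contour is the density level enclosing 95% of kernel mass by
quadrature on that grid. Biome assignment always uses current climate:
biome locations are held fixed under the future scenarios.

# The synthetic world: what it emulates and why

The generator's defaults are the package's study conditions, fixed once:

* **Grid and hemispheres.** Unit-cell grids with the equator at mid-grid
  and poles at the top and bottom rows. With this layout every 2×2
  spatial block spans the full tropical-to-polar gradient, as the
  quadrants of a global calibration area do; a single pole-to-pole
  gradient would instead make block cross-validation an environmental
  extrapolation exercise that no global analysis faces.
* **Layers.** Nine layers mirror the bioclim/land-use/soil predictor
  suite (annual mean temperature, annual range, seasonality,
  warmest-quarter temperature, annual/seasonality/warmest-quarter
  precipitation, natural-vegetation fraction, soil pH). Layer noise is
  regenerated until no within-set pair exceeds $|r| = 0.70$ over land,
  matching the collinearity screen applied to the real predictors.
* **Scenarios.** Futures add +1.8 °C (mild, a sustainability-pathway
  analogue) or +3.7 °C (severe, a fossil-fuelled analogue) to the
  temperature layers, rescale precipitation (×1.03 / ×0.92), reduce the
  natural land-use fraction (5% / 15% mean loss), and hold soil pH fixed.
  Each scenario is realized twice with independent smooth noise fields
  (±0.4 °C sd), playing the role of between-GCM spread.
* **Effort.** Sampling effort is a sum of Gaussian collection centres
  plus a baseline floor of 0.3 × the land-mean kernel intensity,
  normalized to sum to 1: bias spans one to two orders of magnitude, as
  for real effort indices, without underflowing to zero anywhere.
* **Niches.** Species respond to all four climatic variables of predictor
  set 1 with per-axis breadths of 0.6–1.2 land standard deviations and
  optima between the 15% and 85% land quantiles; with four multiplicative
  axes this yields moderate climatic specialists. Niches deliberately
  span every variable the surface range envelope screens: a species
  indifferent to a screened axis would receive pseudo-absences in
  perfectly suitable cells at a severity no real flora exhibits.
* **Record volume.** λ = 500 raw records per species, reduced by
  deduplication and environmental thinning to a few hundred calibration
  points — the data-poor end of the regime global analyses operate in.

What the generator does **not** emulate: real coastlines or dispersal
history, spatial autocorrelation in residual suitability (occupancy is a
deterministic function of the measured layers plus the error fraction),
temporal dynamics, and the taxonomic error structure of real aggregator
data beyond a uniform error rate. Passing tests therefore demonstrate
that the pipeline recovers known niches and computes its statistics
correctly under controlled bias — not that any real flora satisfies the
model's assumptions.

# Problem sizes used by the test-suite

The niche-recovery benchmark runs one predictor set on a 100×100 world
with 30 virtual species (λ = 500) — the scale at which the four families
and the ensemble machinery are exercised end to end. The full-pipeline
integration checks (all five scenario landscapes, both predictor sets,
artifact manifest, determinism) use 40×40 worlds with 3–6 species, and
the distributional and oracle tests use small randomized instances. These
sizes are the package's own choices for a reproducible desk-scale test
suite; all of them are configurable through `run_config()`.

# Numerical choices and degenerate inputs

* Quantiles (SRE bounds, richness summaries) use the linear-interpolation
  definition (R type 7).
* Environmental-filter bins span each variable's range over the species'
  own records; the maximum joins the top bin; a constant variable
  contributes a single bin. Bin edges from the species' occurrence range
  (rather than the landscape range) mirror per-species environmental
  filtering; for real-data use this choice is exposed and flagged.
* The SRE envelope is inclusive at its bounds; presence cells are never
  eligible as pseudo-absences, and pseudo-absences are drawn without
  replacement (duplicated background points add no information and would
  break the presence/absence balance semantics).
* A fold with no held-out presences, or an undefined Boyce index, is
  dropped with a warning; a model with all four folds undefined is
  rejected; a species with no retained model, or no stable $P/E$
  crossing, is flagged and excluded downstream with a logged record.
* Config serialization (YAML) round-trips exactly; every stage seed is
  derived from the master seed plus stage labels, so two runs from one
  configuration produce byte-identical CSV/JSON artifacts.

# Known limitations

* The Whittaker polygon fixture is approximate; absolute biome areas
  should not be interpreted, only scenario contrasts within this package.
* The Boyce-maximization threshold is implemented as the stable
  $P/E \ge 1$ crossing; where the curve is flat near 1 the threshold is
  sensitive to the window discretization (the tests accordingly compare
  binary maps, which are stable, rather than raw thresholds).
* Raster I/O uses multi-page TIFF with a JSON sidecar (band names,
  scale/offset, land mask, continent labels); synthetic grids carry no
  geographic CRS.
* With small modelled pools the hotspot cut-off $\lfloor f M \rfloor$ can
  be 0, making every occupied cell a hotspot; this is the rule's intended
  arithmetic, visible only at toy scale.
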