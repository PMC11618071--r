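---
title: "Methods: community wood density, phylogenetic signal and forest biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community wood density, phylogenetic signal and forest biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`densiforest` implements an analysis chain from two raw inputs — a wood
density trait database (taxon, density in g cm⁻³, source) and tree-level
forest inventory plots (location, plot area, census year, species, DBH) —
to four families of results:

1. **Community-weighted wood density (CWD).** For a plot census, the
   package averages the wood density of its trees weighted by stem basal
   area,
   $$\mathrm{CWD} = \frac{\sum_i \mathrm{WD}_i \, B_i}{\sum_i B_i},
   \qquad B_i = \pi\,(\mathrm{DBH}_i/2)^2 .$$
   Species-level densities are preferred; trees identified only to genus
   (or species missing from the trait table) receive the genus mean, which
   itself averages *species means* rather than raw records so heavily
   sampled species cannot dominate a genus. Plots where fewer than 75 % of
   individuals receive a density are excluded (a plot at exactly 75 %
   coverage is kept — the exclusion rule is strict `<`), and only the
   latest census year of each plot enters the cross-sectional analysis.

2. **Phylogenetic signal.** Pagel's λ is estimated by maximising the
   multivariate-normal likelihood of tip traits under the λ-scaled
   Brownian covariance (off-diagonals times λ, diagonal unchanged), with
   the ancestral mean and rate profiled out analytically at each λ and a
   likelihood-ratio test against λ = 0. Blomberg's K compares the
   observed MSE₀/MSE ratio against its Brownian expectation; significance
   comes from tip permutations scored by the variance of phylogenetically
   independent contrasts. An order-level conservatism test compares each
   order's mean trait against a null of whole-vector tip shuffles
   (two-tailed, `(r+1)/(n+1)` convention, 999 shuffles by default; orders
   under 50 species are reported but flagged untested).

3. **Spatial ensemble mapping with uncertainty.** Plot CWD is aggregated
   to pixels (unweighted mean; half-open, top-left-origin indexing shared
   by every raster operation). Because model residuals of forest trait
   maps are spatially autocorrelated at short range, training uses
   buffer-zone bootstrap subsamples: each ensemble member greedily thins
   the training points in random order until all pairwise great-circle
   distances exceed 50 km, then tunes a random-forest regressor by
   randomized grid search (48 draws from a 240-combination grid by
   default) under ten-fold cross-validation. The final map is the
   unweighted mean over members; the uncertainty map is the pixel-wise
   coefficient of variation (population SD over mean). A Moran's I
   correlogram of smooth-baseline (GAM) residuals over 0–1,000 km bins
   supports the choice of buffer distance.

4. **Extrapolation masks, drivers and biomass.** Training covariates are
   summarised by PCA (centring/scaling/eigenvectors retained); every
   bivariate pair of the leading components (covering > 90 % of variance)
   gets a convex hull of the training scores, and each map pixel is
   projected with the *training* transform and scored by the fraction of
   hulls containing it (≥ 95 % counts as interpolation). Driver analysis
   screens predictors (complete-linkage clustering at |r| > 0.95, then
   iterative VIF < 5), bootstraps permutation importance and standardized
   partial regression coefficients over spatially thinned subsamples (one
   observation per 0.25° cell), and explores disturbance
   context-dependency with a linear-model tree: each node fits
   CWD ~ disturbance, scans candidate covariates over a quantile grid of
   thresholds and accepts the SSE-minimising split only if an F test,
   Bonferroni-corrected, passes α = 0.01 with both children at least the
   minimum node size (500 or 3 % of the data, whichever is larger).
   Biomass follows the volume-expansion chain
   $$\mathrm{TGB} = \mathrm{CWD} \times \mathrm{GSV} \times \mathrm{BEF}
   \times \frac{1}{1-\mathrm{RMF}},$$
   applied per pixel and summed over latitude-corrected spherical cell
   areas; a constant-density counterfactual (0.53 g cm⁻³) isolates the
   contribution of spatial wood density variation as
   $100\,(\mathrm{TGB}_{\mathrm{const}} -
   \mathrm{TGB}_{\mathrm{spatial}})/\mathrm{TGB}_{\mathrm{spatial}}$,
   which — because TGB is linear in CWD — reduces pixel-wise to
   $(0.53/\mathrm{CWD} - 1) \times 100$, an identity the tests exploit as
   an oracle.

# The synthetic world

Real global inventory compilations and covariate stacks are far beyond a
desk-scale package, so every stage is exercised on a generated world with
known truth (`makeSyntheticWorld()`):

* **Phylogeny.** A pure-birth (Yule) tree per clade, joined as the two
  children of the root ("angiosperm", "gymnosperm") and scaled to unit
  depth. Yule rather than birth–death because the tree only needs to
  exercise the Brownian covariance machinery. Synthetic genera, families
  and orders are blocks of neighbouring tips, so taxonomy is
  phylogenetically clustered as in real floras.
* **Traits.** Tip densities are multivariate normal around fixed clade
  means (defaults 0.59 and 0.47 g cm⁻³ with rate σ² = 0.012, giving tip
  SDs near the 0.07–0.14 g cm⁻³ spread of real clades) with λ-scaled
  Brownian covariance. Two deliberate departures from textbook BM keep
  the generator's *contract* — the encoded trait/environment structure —
  stable across seeds: deviations accumulate from each clade's origin
  (block-diagonal covariance), and clade sample means are pinned exactly
  at their targets. Free-running BM lets whole clades drift coherently,
  which on some seeds collapsed the angiosperm–gymnosperm contrast the
  downstream analyses are supposed to recover. Traits are clipped to
  0.05–1.5 g cm⁻³ (the span of real wood); clipping counts are recorded
  because clipping perturbs normality slightly.
* **Landscape.** Congruent raster layers on one lattice (default 64×64 at
  0.25°): temperature as a monotone latitudinal gradient (0–25 °C) plus
  smooth noise, soil moisture and disturbance as smooth logistic fields in
  (0, 1), growing stock volume and root mass fraction with plausible
  magnitudes, biome codes by thresholding temperature and moisture, and a
  smooth-field nodata mask (8 % of cells) shared by all layers.
* **Plots.** Communities assemble by inverse-distance trait filtering:
  species are drawn with weight $1/(|wd - \tau(T)| + \varepsilon)$, where
  the target $\tau(T)$ rises 0.5 % per °C (the encoded CWD–temperature
  slope) and is anchored at the realized trait-pool mean so the target
  band always spans the simulated trait cloud. Gymnosperm weights decay
  with temperature, reproducing the cold-to-warm composition shift. This
  is a sampling model, not a mechanistic community model: its contract is
  only the induced CWD–environment relationship. DBH is truncated
  lognormal (meanlog log 19, sdlog 0.55, all stems > 5 cm; mean ≈ 22 cm
  and 95 % range ≈ 6.5–56 cm, matching published inventory summaries),
  plot areas lognormal with median 25 m², census years uniform. An
  optional planted interaction shifts the filter target by
  ±slope × disturbance on either side of a temperature threshold, for
  context-dependency recovery experiments.
* **Determinism.** All randomness flows from one integer master seed;
  stages re-seed through a hash (`deriveSeed`) so any stage can be
  regenerated independently, and serialized worlds are byte-identical
  across reruns.

What the generator does **not** emulate: real biogeography, dispersal and
demography; plot-size/effort heterogeneity beyond the stated medians;
measurement error in DBH; taxonomic noise (misspellings enter only through
the name canonicalizer's own tests). Passing tests therefore demonstrate
that the estimators recover *known* structure of this kind, not that real
data meet the estimators' assumptions.

## Generator calibration

Community sampling noise shrinks with the number of stems per plot and
with the sharpness ε of the trait filter. Defaults (40 stems expected per
plot, ε = 0.005) were fixed once, during design, so that the encoded
temperature signal is strong enough for a 20-member ensemble on 2,000
plots to reach held-out R² ≥ 0.5 across seeds — the regime the acceptance
analyses probe — while the recovered relative slope stays near the
encoded 0.5 %/°C. They were not revisited afterwards.

# Numerical choices

* λ optimisation is golden-section (`optimize`) on `[0, λ_max]` with
  tolerance 10⁻⁶ and explicit endpoint checks; λ_max is found by
  bisection on Cholesky success (≥ 1 for ultrametric trees). The profiled
  likelihood uses one Cholesky per λ; trees with zero-length terminal
  branches raise a singularity warning and a documented diagonal jitter
  option.
* Randomization p-values use the `(r+1)/(n+1)` convention throughout, so
  no permutation test can return zero.
* The partition tree corrects its F test over **every scanned
  (candidate, threshold) pair**, not only over the candidates: the best
  split is selected from the whole grid, and simulation showed that the
  narrower correction inflates the null false-split rate several-fold
  above its nominal bound. The wider correction holds the empirical null
  rate near α while leaving planted-effect recovery untouched (the
  planted F statistics exceed the corrected threshold by an order of
  magnitude). The threshold grid is deciles by default (configurable);
  split search is O(n log n) per node.
* Ten-fold cross-validation folds are split randomly by row *within* a
  member; spatial independence is already enforced by the 50 km buffer
  thinning of that member's training set. This is a documented
  limitation, not a spatial CV scheme.
* Random-forest permutation importance is computed on per-tree
  out-of-bag samples (via `ranger`), i.e. on data the tree never saw —
  an honest decrease-in-accuracy measure without a separate fold loop.
* The ensemble CV map uses the population (÷ n) standard deviation so
  small member counts remain deterministic and comparable.
* Hull membership counts boundary points as inside (half-plane test with
  ≥ 0), conservative toward interpolation.
* Cell areas use the authalic Earth radius 6,371.002 km with the exact
  spherical band formula, constant within a grid row.
* Rasters are stored as ESRI ASCII grids — a plain-text, single-band
  georeferenced format — under one shared north-up EPSG:4326 convention;
  finite values round-trip bit-exactly at 17 significant digits.

# Open design decisions, resolved

* **Nested versus crossed taxonomic effects.** The variance decomposition
  fixes the nested form family/genus(family)/species(genus), the standard
  reading of a taxonomic hierarchy; components are estimated by REML
  (`lme4`), whose bounded optimisation makes negative components
  impossible (levels with a single category are pinned to 0 with a
  warning).
* **Richness scaling.** Observed species counts scale to a 25 m²
  reference plot with the Arrhenius exponent z = 0.25; z is exposed as a
  parameter because the exact published procedure is unspecified, and
  z = 0 recovers raw counts.
* **CWD over matched trees.** Weights renormalize over trees that
  received a density rather than imputing the unmatched minority; the
  ≥ 75 % coverage guarantee bounds the bias of this choice.
* **Interpolation summary.** Both readings of a "95 %" interpolation rule
  are computed: the per-pixel fraction of hulls containing the pixel
  (thresholded at 0.95 for the mask) and the global share of pixels so
  flagged.
* **Counterfactual scope.** The constant-density biomass holds GSV, BEF
  and RMF fixed and swaps only CWD, the reading that isolates the wood
  density signal; the biomass equation is applied per pixel and then
  summed.
* **BEF table.** Shipped biome→BEF values (1.45/1.35/1.30/1.40 for the
  synthetic boreal/temperate/tropical/dryland codes) are a documented
  placeholder; all internal checks are BEF-agnostic or use explicit toy
  values, and real analyses must supply literature factors.
* **Carbon fraction.** Biomass→carbon conversion defaults to 0.5 and is
  configurable; reported totals state their units (t ha⁻¹ vs tC ha⁻¹).

# Problem sizes

The test suite and the acceptance script run deliberately scaled-down
configurations chosen as the package's own desk-scale defaults: worlds of
64×64 cells with 2,000–4,000 plots and 200-tip phylogenies; ensembles of
20 members with 8 grid-search draws; 50–100 bootstrap replicates for
importance and signal-recovery checks. These sizes keep full runs in the
minutes range on a single CPU while leaving every estimator's behaviour
measurable; all of them scale up by changing arguments, not code.

# Known limitations

* The name canonicalizer is rule-based (plus an optional synonym map); it
  does not attempt fuzzy matching or live taxonomic resolution.
* Only Brownian-family trait models are implemented (no OU or
  early-burst), and no ancestral-state reconstruction.
* The greedy buffer thinning is order-randomized, not optimal thinning;
  subsample sizes therefore vary a few percent between members.
* Genus-only trait records contribute nothing to genus means (which
  average species means by construction).
* The partition tree's F test assumes homoscedastic normal errors within
  nodes; heavy-tailed residuals would call for a robust variant.
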