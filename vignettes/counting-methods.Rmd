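---
title: "Volumetric counting of pollen and ovules from micro-CT scans"
author: "ctcount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric counting of pollen and ovules from micro-CT scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcount)
```

# The problem

Flowers of many plants — orchids most extremely — carry pollen in compact
aggregates (pollinia) of tens to hundreds of thousands of grains, and
ovaries with thousands of ovules. Contrast agents such as phosphotungstic
acid accumulate semi-selectively in these protein-rich structures, so on an
X-ray CT scan they are the brightest voxels and can be isolated by
greyscale thresholding. Counting them is then a volumetric problem: the
total segmented volume divided by the volume of one object gives the object
number, with no need to physically disaggregate or destroy the specimen.

`ctcount` implements that idea end to end: greyscale calibration, the
filtering chain, separation of touching objects, per-object statistics, the
subset-to-whole extrapolation, and the statistical and phylogenetic
comparative analyses applied to the resulting per-flower counts.

# Greyscale calibration

Reconstructed CT volumes have arbitrary grey scales. Two normalizations
are provided.

*Byte scaling* rescales a chosen window `[gmin, gmax]` linearly to 0–255
with clamping, rounding half-up. It is a per-scan operation.

*CT scaling* makes greys comparable **across** scans. A dummy — a pipette
tip filled with the reference liquid (the fixative/contrast solution),
surrounded by air — is scanned under the same settings. The mean greys of
an air window and a reference window determine the unique linear map that
sends air to 0 and the reference to 1000 (targets are configurable; the
procedure fixes only linearity through the two materials). Because the map
is anchored to the materials, any affine detector drift between scans
cancels exactly: a gain-distorted scan recalibrated through its own dummy
is voxel-identical (to float precision) to the undistorted calibration.
This is the invariance checked in the test suite. Calibrated volumes stay
in floating point internally; quantization happens only at TIFF export.

# The counting pipeline

The stage order is fixed: **threshold → 3D median (3×3×3) → 3D Gaussian
(9×9×9) → iterative-threshold separation → object counting**.

Thresholding zeroes voxels darker than the chosen grey value but *retains*
the greyscale of the survivors: the later separation operates on grey
levels, not on a binary mask. The threshold is operator-chosen (the
configuration accepts a number or `"otsu"` for an automatic 256-bin
between-class-variance choice). Both filters use symmetric (mirror)
boundary padding so that object fragments at the scan edge are not
darkened, which would bias volume estimates; the Gaussian kernel is
truncated to its 9³ support and renormalized to sum 1, with σ = 1.5 voxels
by default (≈ 6σ across a 9-wide support, standard for a truncated kernel
of that width).

## Separating touching objects

Aggregated grains form one connected component at the segmentation
threshold. The separator exploits the fact that grain cores are brighter
than the necks between grains (partial-volume dimming plus the point-spread
function): sweeping a threshold *down* from the brightest grey level, each
grain first appears as its own component, grows, and only at the neck grey
level merges with its neighbour. The sweep maintains the complete merge
tree (implemented as a single union-find pass over voxels sorted by grey
level, so the cost is near-linear in the voxel count). Each branch carries
its volume-versus-threshold profile and is *validated* where

* its physical volume lies within the operator's bounds
  `[v_min, v_max]` (µm³), and
* the criterion is optimal: `volume_stability` (default) picks the
  threshold with the smallest relative volume change to the next lower
  threshold — an MSER-style plateau; ties resolve to the higher threshold,
  which favours splitting — while `max_count` takes the highest valid
  threshold on every branch.

When a merged parent and its children both validate, the children are kept:
that is the rule that actually splits grains. Output labels are the
validated components' voxel sets at their selected thresholds, renumbered
deterministically in raster-scan order. Connectivity is 26 by default
(blob counting standard); 6 is available.

**Choosing the volume bounds.** `v_min`/`v_max` are physical, per-specimen
settings. For *well-separated* objects they can bracket the expected object
volume tightly. For *touching aggregates* the branch volume at validation
is the part of the grain **above its merging saddle**, which for tightly
packed grains is only a fraction of the grain volume; `v_min` must
therefore sit well below the expected grain volume (the phantom validation studies use `v̄/30`, with `v_max = 2 v̄`, where
`v̄ = (4/3)π r̄³ (1 + 3 CV²)` is the analytic mean grain volume). Setting
`v_min` near the whole-grain volume silently undercounts aggregates — the
characteristic failure mode of this class of algorithm.

## Counting workflows

*Pollen (two scans).* Individual grains are not resolvable on an overview
scan of the whole pollinium, so a high-resolution scan of a subset is
segmented and separated, giving the subset count `n`. The subset's
segmented volume `V_sub` and the whole structure's segmented volume
`V_tot` are measured **on the overview scan** (the subset's footprint in
overview voxel coordinates is supplied by the operator; scan registration
is out of scope). Then

$$\bar v = V_\mathrm{sub} / n, \qquad N = V_\mathrm{tot} / \bar v ,$$

reported raw and rounded half-up. If the subset is the whole volume the
estimate collapses to the direct count exactly, and the estimate is
invariant to rescaling all voxel spacings (volumes scale equally in
numerator and denominator); both properties are tested.

*Edge handling.* Objects straddling the subset boundary are the classic
stereological hazard. Three rules are provided: `centroid` (default;
count objects whose centroid lies in the window — unbiased when centroids
are observed exactly), `counting_frame` (exclude objects touching the
three low-index faces), and `all`. One subtlety matters in the two-scan
workflow: a grain clipped by the *physical border of the high-resolution
scan* leaves a fragment whose apparent centroid is pulled inside the frame,
inflating the centroid count. The `guardUm` argument restricts counting
(and the matching overview window for `V_sub`) to an interior window; a
guard of about one grain diameter restores unbiasedness. Subset size is a
precision choice: the sampling error of `v̄` is roughly
`CV_vol / sqrt(n)` with `CV_vol ≈ 3 · CV_radius`, so a 3% target needs on
the order of a thousand counted objects, a 10% target a few hundred.

*Ovules (one scan).* Ovules are resolvable on a scan of the whole
gynoecium, so one segmentation yields `n` (automatically, by centroid
membership in the subset window — or an operator-supplied manual landmark
count), `V_sub` and `V_tot`. Because the full scan is available, subset
fragments do not arise and no guard is needed.

*Massulae.* The pollinium's sub-aggregates are resolvable whole; they are
counted directly as connected components within massula-scale volume
bounds, with no extrapolation.

# The phantom generators

Validation data are generated, never downloaded: sphere packings with exact
ground truth (centres, radii, cluster membership, analytic volumes),
rendered at a foreground/background grey level, convolved with a Gaussian
PSF, degraded with additive Gaussian noise (CT reconstruction noise is
approximately Gaussian after filtering; Poisson behaviour can be emulated
by varying the SD) and optional linear shading, then quantized to 8-bit
grey levels. Spheres are packed by random sequential addition with a cell
grid; `touching` mode permits tangency and bounded overlap (default 10% of
the radius sum), `loose` mode enforces a 5% clearance, and `massulae` mode
first places cluster centres with lognormal size loads ("few large, many
small") and then packs grains within clusters; each massula is additionally
rendered as a solid blob, since real massulae are compact stained
aggregates, not loose swarms. Two generator details exist purely to keep
the ground truth honest: the placement margin is *uniform* across grain
sizes (a size-dependent margin would deplete large grains near the domain
boundary and bias subset estimates), and the packed geometry is independent
of all rendering parameters, so truth counts cannot move with noise or PSF
settings.

The benchmark condition used throughout the end-to-end validation tests is the
default `phantomSpec()`: a 256³ volume at 1 µm/voxel with 3000 touching
grains (mean radius 5.5 µm, radius CV 0.15), PSF σ = 1 µm, and additive
noise at signal-to-noise ratio 10 (foreground 180, background 20, noise SD
16). The loose benchmark packs 2000 grains (loose packings jam near 25%
volume fraction, so the touching density is not reachable); the ovary
benchmark holds 800 ovules of radius 5 µm. On these phantoms the two-scan
pollen workflow recovers the true count within 10% (touching) and 3%
(loose), and the single-scan ovule workflow within 5%.

What passing these tests shows — and what it does not. The phantoms
emulate aggregation, blur, noise, shading and calibration drift, with
spherical grains and piecewise-constant tissue greys. They do not emulate
aspherical or hollow grains, beam hardening, ring artefacts, stain
gradients within tissue, or registration error between the two scans.
Recovery on phantoms therefore validates the algorithmic chain, not every
property of real scans.

# The statistical layer

Per-flower counts are compared with a permutation ANOVA on a Euclidean
distance matrix (npANOVA): the total sum of squares implied by the
distances is partitioned over model terms with *sequential* (Type I) sums
of squares in the order written, including interactions (the analysis model
of record is `count ~ species + position + species:position`), and each
term's pseudo-F is referred to its distribution under free permutation of
the raw observations. On univariate data this pseudo-F equals the
classical ANOVA F exactly — an identity the tests check to 10⁻⁹ against
`lm`/`anova`, with `vegan::adonis2` as a second, independent
cross-check — and the permutation p is reproducible given a seed and
bounded below by `1/(n_perm+1)`. The study default is 9999 permutations;
the calibration test scales this to 999 over 1000 null replicates and
requires the empirical size at α = 0.05 to stay within [0.03, 0.07].
Pairwise post hoc tests rerun the permutation test on each level pair and
Bonferroni-correct (`p_adj = min(1, p · n_pairs)`), with compact-letter
grouping.

The exact Mann–Whitney–Wilcoxon test reports both U statistics and
`W = min(U_xy, U_yx)` — the smaller-is-extreme convention of classical
tables — with a two-sided p of twice the smaller exact tail (capped at 1),
switching to the tie-corrected normal approximation (and flagging it) when
ties or large samples preclude exactness. Complete enumeration over all
`choose(n1+n2, n1)` labelings is the test oracle for every size with
`n1 + n2 ≤ 10`. Identical samples give p = 1.

Group summaries report per-species mean, SE (= sd/√N) and variance for
pollen, ovules and per-flower P:O (always computed per flower, never as a
ratio of group means), and N-weighted strategy means whose SE is propagated
as `sqrt(Σ w_i² SE_i²)` with `w_i = N_i/ΣN`. The species-level table of
the eight European orchid species (three rewarding, five deceptive) that
the package's analyses reproduce ships in `inst/extdata/` and is exposed by
`orchidSummaryTable()`.

# The phylogenetic comparative layer

Brownian motion on a rooted tree with branch lengths implies tip covariance
`C_ij` = shared root-to-MRCA path length. Pagel's λ multiplies the
off-diagonal of `C`: λ = 0 means no phylogenetic signal, λ = 1 pure
Brownian motion. For a continuous trait the fit maximizes the
multivariate-normal log-likelihood over (λ, σ², root mean); σ² and the
mean have closed-form maxima at each λ, so the search is one-dimensional
over λ ∈ [0, 1] (the interpretable range; full ML, not REML). The
optimizer brackets the maximum on a coarse grid, refines locally, and
always reconsiders the endpoints; a 1001-point grid is the test oracle.
Simulation recovery is part of the end-to-end validation suite: Brownian traits on
50-tip trees give mean λ̂ ≥ 0.9 over 200 replicates, i.i.d. traits give
median λ̂ ≤ 0.1.

The binary trait (pollination strategy) uses the two-state symmetric Markov
model (equal rates, flat root prior) evaluated by Felsenstein's pruning
algorithm with numerical rescaling; exhaustive summation over all internal
state assignments is the oracle on trees of up to 6 tips. A joint
(q, λ) variant with the λ branch-length transform is available, because
whether the original discrete-trait analysis scaled branches is ambiguous —
the result object records which model was run.

PGLS estimates `β = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y` with `V` the λ-transformed BM
covariance, λ maximized on the residual likelihood (or fixed), coefficient
covariance `σ̂²ₙ₋ₚ (XᵀV⁻¹X)⁻¹` and t-tests on n − p df. At λ = 0 the fit
reduces to OLS exactly; at fixed λ the coefficients match
`nlme::gls` with `ape::corPagel`. Coverage of the true slope at ±2 SE is
≥ 90% over 200 simulated datasets in the validation suite.

The study tree itself (a pruned, time-calibrated phylogeny of the sampled
species) is user input in newick form; analyses here are validated by
parameter recovery on simulated trees rather than by reproducing
supplementary tables that depend on branch lengths not shipped with the
package.

# Numerical and design choices

* Axis order is `(z, y, x)` with z the TIFF page index; ROIs are 0-based,
  half-open `[lo, hi)`, making subset-volume arithmetic exact.
* Voxel spacing is supplied by the operator (µm per voxel, anisotropy
  supported); it never travels inside image files.
* Label maps export as 32-bit float TIFF scaled by 2⁻²⁴ — exact for up to
  16.7 million labels.
* The threshold sweep's step defaults to 1 grey level for integer volumes
  and 1/255 of the swept range otherwise (the finest reproducible sweep for
  8-bit data).
* Counts are rounded half-up for reporting; raw ratios are retained for
  statistics.
* Every stochastic routine takes an explicit seed and restores the caller's
  RNG state; identical inputs give voxel-identical outputs.
* Degenerate inputs fail loudly: empty foreground, zero subset count, zero
  ovule count, coincident calibration greys, single-state discrete traits
  and rank-deficient PGLS designs are all explicit errors rather than NaN
  propagation.

Problem sizes in the test suite were chosen to exercise the benchmark
conditions (256³ phantoms, 200-replicate simulation studies, 1000-replicate
size calibration at 999 permutations) while keeping the full suite runnable
on a single CPU in minutes.

# Known limitations

* The separator assumes brighter-core/dimmer-neck geometry; aggregates of
  uniform intensity with no saddle cannot be split by thresholding alone.
* Volume bounds are mandatory expert input; there is no auto-calibration
  of `[v_min, v_max]`.
* Registration between overview and high-resolution scans is the
  operator's responsibility; the subset footprint is taken on trust.
* PGLS assumes the tree is correct and ultrametric (deviations warn, not
  fail) and shares λ across residuals.
* The npANOVA uses free permutation of raw observations; no restricted
  permutation schemes for nested designs.
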