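---
title: "Feature-similarity gradients of neonatal cortical microstructure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-similarity gradients of neonatal cortical microstructure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`neovb` maps local homogeneity of cortical microstructure in neonates. At
every vertex of a cortical surface it measures, with the Vogt-Bailey (VB)
index, how smoothly a six-dimensional microstructural feature vector varies
across the tissue voxels around that vertex. Low VB marks sharp feature
transitions (candidate areal borders); high VB marks graded change
(homogeneous cortex). Group differences in the resulting per-vertex maps —
the motivating application is preterm versus term-born infants scanned at
term-equivalent age — are then tested with a vertex-wise GLM under
permutation inference with threshold-free cluster enhancement (TFCE) and
familywise error (FWE) correction.

This vignette documents the model, its assumptions, the tunable parameters,
the synthetic-data generator that provides ground truth, and the numerical
choices the implementation makes where the method description leaves a
design open.

# The feature vector

Six diffusion-derived metrics describe each brain-tissue voxel: fractional
anisotropy (FA), mean/axial/radial diffusivity (MD, AD, RD, mm²/s), and the
NODDI neurite density and orientation dispersion indices. NDI and ODI are
first modulated by the tissue fraction `1 − ISO` (ISO being the NODDI
isotropic water fraction), so neurite properties are weighted by actual
tissue content; `tissue_fraction()` and `modulate()` implement this.
`stack_channels()` then z-scores every channel over the tissue mask and
stacks them in the fixed order (FA, MD, AD, RD, NDI_mod, ODI_mod).

Two normalisation choices are deliberately fixed:

* **Z-scoring is per subject**, over that subject's masked voxels. Because
  the searchlight operates in native space, a per-subject normalisation is
  the only population-free choice; whether a whole-brain or cortex-only mask
  is used is up to the caller via the mask argument.
* **Population SD** (denominator `n`) is used. Scale cancels inside the
  Pearson affinity, so the choice is cosmetic, but it must be pinned for
  bit-reproducibility.

Fitting the DTI and NODDI models themselves is out of scope: the six metric
maps are inputs (or are synthesised).

# The VB searchlight

At vertex `v` with one-ring neighbours `N(v)` (the vertices sharing a mesh
edge with `v`):

1. **Hybrid neighbourhood.** Each vertex of `{v} ∪ N(v)` is matched to its
   nearest voxel by applying the inverse voxel-to-world affine and rounding
   each index coordinate (ties away from zero). Matched voxels outside the
   tissue mask, or outside the 3×3×3 index cube centred on `v`'s own matched
   voxel, are discarded; duplicates are merged. The cube bound (at most 27
   voxels) keeps the neighbourhood compact even where surface vertices
   cluster, and the volumetric reconstruction avoids the spatial
   correlations that purely surface-based neighbourhoods inherit from
   gyrification geometry. The cube is an index-space construct, so
   anisotropic voxels use the index cube, not a metric ball.
2. **Affinity graph.** All voxel pairs receive weight
   `max(0, r(x_i, x_j))`, the Pearson correlation of their 6-vectors across
   the feature dimension with negative values clipped to zero; a
   zero-variance vector gets affinity 0. The clipped-Pearson form is
   isolated behind `affinity()` so an alternative similarity can be swapped
   in without touching the spectral code.
3. **Scaled algebraic connectivity.** With `L = D − W` the unnormalised
   graph Laplacian, the VB index is `λ₂(L) / n`, `n` being the node count.
   Division by `n` is the unique linear scaling under which the
   maximal-homogeneity graph — complete with unit weights, `λ₂ = n` — scores
   exactly 1, and a disconnected neighbourhood (a sharp border splitting the
   searchlight) scores 0.

Numerical choices: eigenvalues come from a dense symmetric
eigendecomposition (`n ≤ 27` makes iterative solvers pointless); eigenvalues
above `−1e-10` are clipped to zero; neighbourhoods with fewer than 3 usable
voxels give a missing value (`λ₂` of a 2-node graph is just twice the single
affinity, which measures nothing about gradation), as do vertices whose
centre voxel falls outside the mask. `vb_map()` never aborts on unusable
vertices; it records them as missing alongside a per-vertex
neighbourhood-size diagnostic.

# Surface smoothing

Individual VB maps are smoothed before inference with a Gaussian geodesic
kernel of FWHM 4 mm (`σ = FWHM / (2√(2 ln 2)) ≈ 1.70` mm). Distances are
graph-geodesic (Dijkstra over mesh edges with Euclidean edge lengths) —
standard for surface smoothing and immune to cross-sulcal leakage, which 3D
Euclidean distances would permit. The kernel is truncated at `3σ`
(discarding < 1.2% of kernel mass) and renormalised to sum to one, so
constant maps are reproduced exactly; missing neighbours are dropped with
the remaining weights renormalised, and missing vertices stay missing. A
single kernel pass realises the nominal FWHM directly — verified on a
0.5 mm planar lattice, where the impulse response's measured full width at
half maximum is 4 mm to within one lattice spacing (this is also what
`scripts/acceptance.R` recomputes).

# Group inference

The design matrix holds an intercept, the group indicator (preterm = 1),
centred postmenstrual age at scan, and a centred 0/1 sex indicator. The
per-vertex statistic is the OLS t for the group contrast; both one-sided
directions (preterm > term, term > preterm) are evaluated, mirroring the
separate reporting of the two directions in studies of this design.

Permutation inference follows the Freedman-Lane scheme (the default of the
PALM tool this stage re-implements at desk scale): the nuisance-only model
is fitted, its residuals are permuted across subjects, the nuisance fit is
added back, and the full-model t and its TFCE enhancement are recomputed per
shuffle. The null distribution is the maximum TFCE over vertices, giving
FWE-corrected p-values `(b + 1)/(m + 1)` — never zero. When the requested
number of shuffles reaches the number of distinct permutations, the test
enumerates exhaustively (with a warning) and reports exact p-values `b/m`
with the identity included. Permutations are drawn in canonical subject-id
order, making results invariant to input row order.

TFCE uses `E = 1`, `H = 2` — the established surface defaults of the
method — with integration step `dh = max(stat)/100`; vertex extent is
measured as surface area (one third of each incident triangle's area per
member vertex) and connectivity is one-ring. Negative-direction enhancement
processes the negated statistic; there is no two-sided TFCE.

Across the two hemispheres, which are analysed as fully independent runs on
separate cohorts, significance is declared at the Šidák-corrected level
`1 − (1 − α)^(1/2) = 0.0253` for `α = 0.05`. A per-vertex nuisance map such
as sulcal depth can be regressed out of the VB maps beforehand with
`residualize_nuisance_map()`, which preserves each vertex's grand mean.

# The synthetic-data generator

Real neonatal cohorts are restricted data, so validation rests on synthetic
cohorts with known ground truth. The generator emulates three features of
the real analysis problem:

* **Piecewise-homogeneous cortex.** An icosphere stands in for a
  hemisphere; geodesic-Voronoi patches (farthest-point-sampled seeds, then
  a multi-source Dijkstra flood that guarantees connected patches) stand in
  for cortical areas. Per-patch mean feature vectors sit at exact mutual
  distance `patch_mean_separation`, realised as scaled standard-basis
  vectors rotated by a fixed orthogonal matrix so every channel varies
  across patches (an unrotated basis would leave channels beyond the patch
  count constant, degenerate under z-scoring). This construction caps
  `patch_count` at the channel count.
* **A group homogeneity effect.** Voxel features are patch mean + PMA trend
  + Gaussian noise; in designated effect patches the preterm group's noise
  SD is multiplied by `homogeneity_boost ∈ (0, 1]`. This directly
  manipulates the quantity VB measures — more homogeneous microstructure in
  the preterm group, the direction reported in neonatal cohorts — with
  `boost = 1` yielding an exactly exchangeable null cohort.
* **Covariates.** PMA at scan enters as a linear per-channel shift and sex
  alternates across subjects. Note that a constant per-channel shift is
  removed exactly by per-subject z-scoring, so PMA is by construction a
  *null* covariate with respect to VB here: it exercises the nuisance
  machinery without biasing the group contrast.

Default study conditions (chosen once, as a realistic desk-scale stand-in,
and used by the validation suite): sphere radius 20 mm and 2 mm isotropic
voxels — matching the proportions of a neonatal hemisphere imaged at
typical neonatal dMRI resolution, so that the prescribed 4 mm FWHM
smoothing has a realistic spatial footprint relative to the surface — a
subdivision-3 icosphere (642 vertices, ~2.6 mm vertex spacing ≈ 1.3 voxels),
6 patches with 2 effect patches, `within_patch_sd = 1`,
`patch_mean_separation = 3`, `homogeneity_boost = 0.5`, 15 subjects per
group, PMA uniform on 37–43 weeks. The voxel grid encloses the mesh with a
2-voxel margin; the mask is the shell of voxels within one voxel size of the
surface; each masked voxel inherits the patch of its nearest vertex. The
noise-free limit `within_patch_sd = 0` is supported exactly and underpins
the sharpest contract: interior vertices score VB = 1, boundary-crossing
searchlights score below 1.

What the generator does **not** emulate: realistic dMRI signal formation and
scanner noise, partial-volume/CSF contamination, cortical folding (the
sphere has no gyri, so gyrification-specific artifacts cannot arise here by
construction), and between-dataset harmonisation. Passing tests therefore
demonstrate the statistical machinery — calibration, recovery, invariances —
not robustness to those acquisition-level effects.

# Validation experiments and problem sizes

The test suite runs two cohort-level experiments, scaled down from the
10,000-shuffle full analysis to fit a single CPU:

* **Null calibration.** 200 null cohorts (`boost = 1`, 10 per group) on a
  small mesh (subdivision-1 icosphere, radius 5 mm, 2 mm voxels, 4 patches)
  with 200 shuffles each. The familywise false-positive rate of the
  one-sided preterm > term test at the 0.0253 threshold must be consistent
  with 0.0253 (exact binomial 95% CI). The one-sided test is the unit whose
  error rate the threshold controls; testing both directions would target
  ~0.05. A 340-cohort pilot of this configuration measured 0.023.
* **Recovery.** 10 effect cohorts at the default study conditions
  (`boost = 0.5`, 15 per group, 200 shuffles): mean sensitivity for the
  planted effect mask must be at least 0.5 and mean false-discovery
  proportion at most 0.2. Residual false discoveries are concentrated in
  the one-ring of the patch boundary, where 4 mm smoothing legitimately
  spreads the effect.

# Known limitations

* The exact "modified Pearson correlation" of the original VB toolbox is
  not reproduced bit-for-bit; this package implements clipped Pearson
  across the six features, the behaviour its own contract specifies, behind
  the `affinity()` seam.
* The `λ₂/n` scaling is likewise this package's contract; other VB
  implementations may scale differently, so absolute VB values should be
  compared only within one implementation.
* Vertices are matched to voxels by nearest-index rounding; no partial
  volume weighting or surface-normal sampling is attempted.
* Inference assumes exchangeable subjects under the null: no
  exchangeability blocks, variance smoothing, or tail approximation are
  provided.
* GIFTI support covers the arrays this package exchanges (surfaces and
  per-vertex metrics); CIFTI and FreeSurfer formats are not read.
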