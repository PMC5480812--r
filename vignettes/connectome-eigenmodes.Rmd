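---
title: "Laplacian eigenmodes of structural connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laplacian eigenmodes of structural connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectralconn)
```

## The model

A structural connectome is an undirected weighted graph: nodes are
gray-matter regions, and the weight between regions $i$ and $j$ is a
streamline density derived from tractography counts,

$$A_{ij} = \frac{S_{ij} + S_{ji}}{2\,(V_i + V_j)},$$

where $S_{ij}$ is the number of streamlines seeded in region $i$ that reach
region $j$ and $V_i$, $V_j$ are the region volumes. The volume normalization
prevents large regions from looking strongly connected merely because they
seed or receive many streamlines; averaging the two directions makes the
graph undirected (`build_adjacency()`).

Any linear first-order spread process on this graph obeys the network
diffusion equation

$$\frac{dx}{dt} = -\beta L x, \qquad L = \mathrm{diag}(A\mathbf{1}) - A,$$

whose solution is diagonal in the eigenbasis of the graph Laplacian $L$:
$x(t) = Q e^{-\Lambda\beta t} Q^{\top} x_0$ (`solve_network_diffusion()`).
$L$ is symmetric positive semidefinite with zero row sums; the constant
eigenvector with $\lambda_1 = 0$ carries the conserved total, and each
additional connected component contributes another zero eigenvalue. The
reciprocal eigenvalue $1/\lambda_i$ is the characteristic time of mode $i$,
so the few lowest ("slowest") eigenmodes dominate the persistent,
whole-network patterns of any linear spread — they are the objects this
package characterizes. $\beta$ only rescales time and defaults to 1; all
spectra and importance values are computed on $L$ itself.

On a two-hemisphere network whose interhemispheric (callosal) coupling is
weak relative to intra-hemispheric connectivity, the second eigenmode is the
interhemispheric gradient: the sign of $v_2$ separates left from right
nodes, and $\lambda_2$ measures the rate of left–right diffusion. The next
modes follow the remaining large-scale geometric gradients
(anterior–posterior, superior–inferior) provided those directions are not
spectrally degenerate.

## Eigenmode matching, angle variance, and spectra

Eigenvector *rank* can switch between subjects (or after a perturbation)
when neighboring eigenvalues are close, without any real change in the
eigenstructure. `match_eigenmode()` therefore identifies a reference mode in
another decomposition by the largest absolute inner product within a rank
window (default ±2, which in practice always suffices; the window is
configurable and may be infinite). Since an eigenvector is defined only up
to sign, the sign is chosen to make the inner product non-negative.

Cross-subject reproducibility of a mode is quantified by the angle between
a subject's matched eigenmode and the mode of the cohort's mean connectome
(`angle_variance()`), minimized over the matching window and over sign, and
reported in degrees with a t-based 95% confidence interval. The inner
product is clipped to $[-1, 1]$ before `acos` to absorb floating-point
rounding. For comparing eigenvalue distributions across subjects with
different overall connectivity scales, each spectrum is normalized by its
mean (`normalize_spectrum()`). The normalizing mean includes the zero
eigenvalue(s) by default; because disconnection changes how many zeros a
spectrum has, group comparisons report the nonzero-mean variant alongside
(`compare_groups()`), and the two conventions never disagree on orderings in
the analyses here.

Tie-breaking and degeneracy: eigenvalues are sorted ascending with LAPACK's
deterministic ordering; each eigenvector's sign is canonicalized (largest
magnitude entry positive) so repeated runs are bitwise reproducible.
Degenerate eigenvalues are returned with an orthonormal basis of their
subspace, and matching operates on absolute inner products across the whole
window, which is the right behavior when a subspace rotates under
perturbation.

## Geometric null networks

Much of connectome structure is explained by a cost–wiring rule: connection
weight falls with distance. To test whether an observed eigenmode property
goes beyond that rule, `geometric_null()` builds random networks that
preserve the distance–weight profile exactly: all node pairs are sorted by
inter-centroid Euclidean distance into discrete bins (default 100; 10 and
1000 behave equivalently in our checks), and weights are permuted uniformly
within each bin. Bins are quantile bins (equal pair counts) so every bin has
shuffle partners; equal-width binning is available. Zero-weight pairs
participate in the shuffle by default — this preserves edge density within
each distance stratum, which is part of the cost-wiring relationship; a
nonzero-only option exists for sensitivity analysis. The per-bin weight
multiset, the total weight, and the binned distance–weight curve are
preserved exactly; hemispheric organization and hub structure are destroyed.

## Lesion simulation and importance maps

Edges are embedded in space as voxel trajectories. For each tractography
direction the top 95% of an edge's non-zero voxels, ranked by streamline
count, are retained (`ceiling(0.95 n)` voxels — the weakest 5% by rank are
dropped; we read the threshold as a count of voxels, not a fraction of
streamline mass), and the consensus mask is the union of the two retained
sets (`consensus_edge_mask()`).

A virtual lesion is a sphere (default diameter 12 mm) placed at a
white-matter voxel. Every edge whose consensus mask intersects the sphere is
weakened by

$$A_{ij} \to A_{ij}\,(1 - s\,f_{ij}),$$

where $f_{ij}$ is the fraction of the edge's consensus voxels inside the
sphere (edge "volume" is a unique-voxel count, since trajectories are voxel
sets) and $s \in (0, 1]$ is the stoppage parameter — how completely damaged
tissue blocks streamlines. The importance of the voxel for eigenmode $k$ is
the decrease of the matched eigenvalue after re-eigendecomposing the
lesioned Laplacian (`importance_at()`); matching guards against rank
switches. We deliberately use a full re-decomposition rather than
first-order perturbation theory; the first-order estimate
$v_k^{\top}\Delta L\, v_k$ serves as an independent oracle in the tests,
agreeing within 10% whenever $s f \le 0.05$ on every edge. In degenerate
near-tie situations a matched importance can be slightly negative; values
are reported unclipped with the matched index attached rather than silently
clipped. If a lesion disconnects the graph, the value is still returned and
flagged.

`importance_map()` evaluates this at every white-matter voxel (any voxel
covered by a consensus mask), optionally on a strided sub-grid;
`stoppage_sweep()` batches modes and stoppage values, reusing the sphere
geometry across stoppages and one eigendecomposition per (voxel, stoppage)
across modes. Importance scales exactly linearly with a global weight
rescaling, so map correlations are scale-free.

## Reliability (ICC) and tract aggregation

Voxelwise maps are aggregated to tract means over a label volume
(`aggregate_importance_by_tract()`); any atlas on the working grid is
accepted, and the synthetic generator emits a toy partition of its
white-matter voxels into octant blocks standing in for an anatomical tract
atlas. Test–retest reliability of the tract means uses the variance-ratio
intraclass correlation: with two scans per subject,

$$\sigma_{1} = \overline{\mathrm{Var}(\{x_{s,1}, x_{s,2}\})}, \qquad
  \sigma_{2} = \mathrm{Var}_s\!\left(\tfrac{x_{s,1}+x_{s,2}}{2}\right), \qquad
  \mathrm{ICC} = \frac{\sigma_2}{\sigma_1 + \sigma_2}.$$

Sample variances ($n-1$) are used throughout; with two scans the ICC ratio
itself is invariant to that convention, but the convention matters for the
$\sigma$ values and is therefore fixed. This is the direct variance-ratio
form, not the ANOVA ICC(2,1); the two differ in general, and we implement
the former deliberately. More than two scans are accepted as a natural
extension (per-subject variance over all scans). Clinical reporting bands
(poor < 0.4, fair-to-good 0.4–0.75, excellent > 0.75) are labels only; no
computation depends on them.

## Rich-club edges and density maps

Rich-club analysis here needs only the node set: by default the top 15% of
nodes by binary degree, with weighted degree, an explicit threshold, or —
the primary pathway on synthetic data, where the generator knows its planted
hubs — an explicit node list. Edges classify as rich-club (both endpoints
rich), feeder (one), or local (neither). `edge_density_map()` counts, per
voxel, the edges of a class whose consensus mask covers it; the class maps
sum voxelwise to the all-edges map by construction. Density and importance
maps are compared by Pearson correlation over a white-matter mask with a
Fisher-z 95% interval (`correlate_maps()`). On synthetic data the
white-matter mask is the union of consensus masks — a stand-in for an
anatomically defined mask, not an equivalence. Normalized rich-club
coefficients against rewired nulls are out of scope.

## Virtual callosotomy and callosal agenesis

`virtual_callosotomy()` removes every edge whose consensus trajectory
crosses the midline sagittal plane (a voxel within half a voxel spacing of
the plane), cutting affected edges entirely — exclusion-mask semantics:
streamlines through the callosum are removed, so a purely callosal edge
retains zero weight. The plane may be restricted to a z-range because the
corpus callosum is a bounded midline structure; the default is the full
plane. This restriction is what makes a synthetic agenesis variant
(`generate_agcc_variant()`) possible: callosal edges are removed and a
fraction of their weight is re-added along detour trajectories that cross
the midline inferior to the callosal region — the synthetic analog of the
compensatory tracts described in congenitally acallosal brains. Any
interhemispheric path must cross the midline plane somewhere, so
compensation is only expressible with a bounded callosal cut; detour
geometry is validated at generation time.

Group comparisons of the normalized second eigenvalue (left–right diffusion
rate) report per-group means with 95% confidence bounds and pairwise
two-sample t-tests at $\alpha = 0.05$, uncorrected. On cohorts where the
agenesis variant receives compensation, the expected ordering is
control > agenesis > callosotomy; this is a generator-conditional property
(the generator plants the compensation), not an external validation.

After hemispheric disconnection, a bilateral eigenmode splits into two
modes, one per hemisphere — the block-diagonal limit of the Laplacian.
`detect_mode_splitting()` reports, per control mode, the best-matching
lesioned modes and their hemispheric support fractions (share of squared
eigenvector mass per hemisphere); a split requires the two best matches to
hold at least 0.9 of their mass in opposite hemispheres. The threshold sits
below the exact-limit value 1.0 to absorb residual coupling.

## The synthetic generator

No imaging data ship with the package; every analysis stage is exercised on
generated connectomes (`generate_connectome()`, `generate_cohort()`). The
generator emulates, at desk scale, the features the analyses rely on:

* **Two mirrored hemispheres.** Half the nodes are placed uniformly in the
  right half-grid with at least 16 mm between centroids (regions of an
  ~80-node parcellation are about that far apart); the left hemisphere is
  the exact mirror. The default grid is 64³ voxels at 2 mm.
* **Distance decay and sparsity.** Directed streamline counts are Poisson
  with expectation $\propto e^{-d/20\,\mathrm{mm}}$; edges exist with
  probability $e^{-d/60\,\mathrm{mm}}$, so short-range connectivity is
  dense and long-range sparse, giving a monotone distance–weight profile.
* **Callosal bottleneck.** Interhemispheric pairs get reduced existence
  probability (×0.3) and expected counts (×0.5); homotopic mirror pairs
  always connect. The resulting cross-hemisphere weight share (~3–8%)
  makes the second eigenmode separate the hemispheres exactly.
* **Anisotropic geometry.** The node cloud is widest anterior–posterior and
  flattest superior–inferior, so the low diffusion gradients
  (interhemispheric, then anterior–posterior, then superior–inferior) stay
  spectrally separated rather than degenerate — the regime in which
  matched-mode analyses are meaningful.
* **Volumetric trajectories.** Edges are straight (intra-hemispheric) or
  single-bend polylines routed through superior midline "callosal" voxels
  (interhemispheric), dilated into 3 mm-radius tubes. Fiber bundles have
  finite cross-section; the tube bounds the fraction of an edge a 12 mm
  lesion can remove, keeping lesion perturbations in the small-perturbation
  regime the importance analysis assumes. Per-voxel streamline counts are
  Poisson draws for each direction, so the two directions threshold
  differently and the consensus union is nontrivial.
* **Hubs.** A planted, hemisphere-symmetric hub set (default 8 nodes) gets
  multiplicatively boosted counts, creating rich-club structure whose
  ground truth is known to the tests.
* **Noise model.** Subject- and scan-level variability are multiplicative
  log-normal on weights (default sd 0.3 and 0.1): streamline counts are
  positive and right-skewed, and additive Gaussian noise would break
  non-negativity. Scans share their subject's zero pattern, and all
  subjects share one template geometry and grid — the synthetic analog of
  registered subjects, since registration is out of scope.

What the generator does **not** emulate: curved fasciculi and crossing-fiber
geometry, distance-dependent tractography bias, partial-volume effects,
subject-specific anatomy (all subjects share a template), or any realistic
signal model. Passing tests therefore demonstrate the correctness and
internal consistency of the algorithms under the stated statistical
structure, not agreement with any particular imaging dataset — headline
numbers from acquired DTI cohorts (raw eigenvalue scales, tract-level ICC
magnitudes, group p-values) are functions of those data and are not
reproduced here.

## Numerical choices and problem sizes

Symmetry and positive-semidefiniteness checks use a relative tolerance of
1e-9, appropriate for double-precision eigensolves; zero eigenvalues are
identified at the same relative tolerance. Eigendecomposition is LAPACK's
symmetric solver via `eigen(symmetric = TRUE)`. Disconnected inputs are
legal everywhere and flagged rather than rejected. A connectome draw that
comes out disconnected is regenerated (up to a retry limit) with derived
seeds; all randomness flows from one root seed through derived substreams,
so every result is bitwise reproducible.

The shipped tests and experiment defaults use 16–80 nodes, 32³–64³ grids at
2 mm, stride 2–4 lesion grids, and cohorts of 3–10 subjects — sizes chosen
so a full run completes in minutes on a single core while leaving every
algorithmic path exercised at the 80-node scale of a standard subcortical+
cortical parcellation.
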