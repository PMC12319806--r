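---
title: "Tract-specific aggregate g-ratio mapping: model and methods"
author: "tractgr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract-specific aggregate g-ratio mapping: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The aggregate g-ratio of a white matter tract — the area-weighted ratio
of inner (axon) to outer (axon + myelin) fiber diameter — modulates
conduction velocity and can be estimated in vivo by combining a
myelin-sensitive map (here MTsat) with multi-shell diffusion MRI. The
conventional route, *tractometry*, samples a voxel-wise g-ratio map
along each streamline and averages. Because most white matter voxels
contain several crossing fiber populations, tractometry mixes the
properties of all fibers in every voxel it touches, biasing tract values
toward each other.

`tractgr` implements the *tract-specific* alternative: model each
voxel's signal as a non-negative linear combination of per-streamline
contributions (the COMMIT idea), so that crossing tracts are separated
at the fit level. Per-streamline myelin and intra-axonal volumes are
then summed per connectome edge and combined into an edge g-ratio. A
synthetic crossing-fiber phantom with exact ground truth makes every
stage testable without any acquisition.

## The model

Three linear non-negative solves share one geometric primitive: the
in-voxel length of every streamline (`voxelize_streamline()`).

1. **Filtering / tract ICVF.** The b0-normalized multi-shell signal is
   fit with a stick–zeppelin–ball dictionary: one *stick* column per
   streamline (restricted compartment, entries
   $\ell_{iv}\,e^{-b D_\parallel (\hat g\cdot\hat u)^2}$), one
   *zeppelin* column per voxel orientation cluster (hindered,
   $e^{-b(D_\perp + (D_\parallel-D_\perp)(\hat g\cdot\hat u)^2)}$), and
   one *ball* per voxel and isotropic diffusivity. Diffusivities are the
   standard white matter values
   $D_\parallel = 1.7\times10^{-3}$, $D_\perp = 0.51\times10^{-3}$,
   $D_\mathrm{iso} \in \{1.7, 3.0\}\times10^{-3}\,$mm$^2$/s (gray-matter-
   and CSF-like partial volume). Streamlines with zero fitted weight are
   removed; the tract ICVF map is restricted/(restricted + hindered)
   fitted volume per voxel, the intra-neurite convention — the isotropic
   compartment is excluded from the denominator.

2. **Myelin CSA.** With an MVF map in hand, the linear system
   $\sum_i \mathrm{CSA}_i\,\ell_{iv} = \mathrm{MVF}_v \cdot V_\mathrm{voxel}$
   is solved for non-negative per-streamline myelin cross-sectional
   areas; myelin volume is $\mathrm{MV}_i = \mathrm{CSA}_i \times L_i$.

3. **True axonal CSA.** Myelin is diffusion-invisible, so the
   b0-normalized diffusion signal is scaled by $(1-\mathrm{MVF})$ before
   the second diffusion solve (`myelin_correct_signal()`; the fit does
   not re-normalize). Restricted weights are then *true* intra-axonal
   CSAs and $\mathrm{AV}_i = \mathrm{CSA}_i \times L_i$.

Edge quantities are sums over the streamlines connecting a node pair,
and the edge g-ratio is
$g = \sqrt{\mathrm{AV}/(\mathrm{AV}+\mathrm{MV})}$ — computed after
aggregation, because g is not additive.

### MTsat and calibration

MTsat follows the standard spoiled-GRE estimator
$\mathrm{MTsat} = (S_0\,\alpha B_1/S_\mathrm{MTw} - 1)\,TR/T_1 -
(\alpha B_1)^2/2$ (defaults $\alpha = 6^\circ$, $TR = 27$ ms, the
MT-weighted protocol values). MVF is $\alpha_\mathrm{calib}\times
\mathrm{MTsat}$. The calibration factor comes from a reference region
assumed to have $g_\mathrm{ref} = 0.7$ (the splenium convention):
inverting $\mathrm{AVF} = (1-\mathrm{MVF})(1-\mathrm{ISOVF})\,
\mathrm{ICVF}$ and $g = \sqrt{\mathrm{AVF}/(\mathrm{AVF}+\mathrm{MVF})}$
at fixed $g_\mathrm{ref}$ gives, with $c = (1-\mathrm{ISOVF})\,
\mathrm{ICVF}$,
$$\mathrm{MVF}^\ast = \frac{c\,(1-g_\mathrm{ref}^2)}
{g_\mathrm{ref}^2 + c\,(1-g_\mathrm{ref}^2)},$$
and the per-voxel factor $\mathrm{MVF}^\ast/\mathrm{MTsat}$. This
closed form is the unique choice consistent with the two equations.
Voxels are selected by FA > 0.8 inside the ROI; factors are averaged
within subject first, then across subjects with equal weights. The
closure property — recomputing g in a homogeneous ROI returns exactly
$g_\mathrm{ref}$ — is the package's primary acceptance check
(`scripts/acceptance.R`).

## The phantom: a stated world

`build_phantom()` generates the synthetic dataset all tests run on.

* **Geometry.** Default grid $16^3$ voxels at 1 mm. Two 50-streamline
  bundles with $g = 0.60$ and $0.80$ cross in one axial plane at about
  20°; streamlines are rigid perpendicular-offset copies of the
  centerline (Gaussian jitter, sd 0.45 voxel). The 20° angle keeps the
  two stick orientations identifiable to the fit (at shallower angles
  the axon/hindered trade between bundles becomes numerically flat),
  while the 0.45-voxel jitter widens both tubes enough that their
  partial-volume corridor covers more than half of each bundle's course
  — the regime where the per-streamline *median* used by tractometry is
  genuinely pulled toward the crossing bundle. Both choices were fixed
  from this geometric reasoning, not tuned against test outcomes.
* **Microstructure.** Per-streamline fiber cross-section 0.008 mm²
  (about 40% fiber volume per bundle in core voxels — dense but leaving
  room for the crossing), split into axon and myelin by
  $g^2 = \mathrm{CSA_{axon}}/\mathrm{CSA_{total}}$. Free-water ISOVF is
  a uniform 0.05, a typical deep-white-matter value. Volume fractions
  are checked to sum to at most 1 per voxel; denser specifications are
  rejected.
* **MTsat.** Synthesized as MVF/20 — i.e. the phantom's true
  calibration factor is 20, inside the 19–20 range typical of in-vivo
  calibrations — so the calibration stage is exercised non-trivially.
* **Spurious streamlines.** Ten quadratic-Bezier arcs connect random
  node labels out of the bundle plane, steep enough (apex height
  max(3.5 mm, 0.6 × endpoint distance)) that their local orientation in
  any voxel they share with a bundle differs by at least 30°. The DWI
  fit should, and does, assign them zero weight; this mirrors COMMIT's
  false-positive filtering. Real tractograms contain subtler false
  positives; the 30° construction is a testbed, not a claim about
  probabilistic tractography output.
* **Signal.** The forward simulator composes exactly the compartments
  the fitting dictionary contains (same orientation clustering code), so
  noiseless recovery is well-defined: restricted sticks carry
  CSA × length, the extra-axonal volume rides zeppelins split across
  orientation clusters in proportion to cluster axon volume, free water
  is a CSF ball, and fiber-free water a gray-matter ball. The total b=0
  signal of a voxel is $(1-\mathrm{MVF}) V_\mathrm{voxel}$: myelin water
  is invisible. Rician noise (magnitude MRI) is optional, with a
  Gaussian variant for linear-regime tests.
* **Calibration phantom.** A separate dense single bundle
  ($\approx$ 80% fiber volume, tight 0.2-voxel jitter, $g = 0.7$,
  ISOVF 0.01) whose voxel tensor FA exceeds the 0.8 selection threshold
  — a splenium stand-in. The default crossing phantom's bundles are
  deliberately less dense and never reach FA 0.8.

What a green phantom test does **not** establish: realistic brain
geometry, fiber dispersion or fanning, susceptibility/motion artifacts,
resolution mismatch between DWI and MTsat, or tractography errors other
than the constructed spurious arcs.

## Numerical choices

* **Solver.** NNLS by FISTA-style accelerated projected gradient with
  adaptive restart; KKT stopping at tol $10^{-8}$ (relative to
  $\max(1, \|A^\top y\|_\infty)$), max 5000 iterations by default, with
  a warning and the best iterate on non-convergence. Small systems get
  an exact active-set refinement; its normal equations carry a relative
  ridge of $10^{-10}$, which resolves exactly duplicated streamline
  columns by an even split. The three whole-tractogram pipeline solves
  disable the refinement (the projected-gradient iterate, like COMMIT's
  solver, distributes weight across redundant near-parallel streamlines
  instead of collapsing onto a sparse vertex) and request a deeper
  budget (50000 iterations): the noiseless phantom systems have long
  flat valleys and the bundle-level sums continue improving well past
  the general-purpose default.
* **Zero-weight removal** uses weight < $10^{-10}\times$ max weight:
  "zero" is solver-dependent at finite precision. A consequence worth
  knowing: with many nearly duplicate streamlines the least-squares
  optimum is sparse, so a substantial fraction of *redundant* true
  streamlines can legitimately receive zero weight. Bundle-level
  volumes are conserved (the surviving streamlines absorb them); tests
  assert bundle survival and volume conservation rather than complete
  per-streamline retention.
* **Hindered orientation clusters**: per voxel, segment directions are
  clustered greedily with a 15° antipodal threshold, one zeppelin
  column per cluster; per-streamline hindered columns would be rank
  deficient. Within-voxel direction = normalized chord of the
  within-voxel piece.
* **Streamline–voxel intersection** splits polyline segments exactly at
  voxel faces (half-open cubes); in-voxel lengths sum to the arc length
  to $10^{-9}$ relative. Out-of-grid portions are clipped and flagged.
* **Tractometry** resamples at 0.5 mm (the tractography step) and
  interpolates trilinearly; NaN corners (outside tissue) are dropped
  and the remaining corner weights renormalized, so one-voxel-thick
  tracts remain sampleable; a sample is NaN only when all corners are.
  Per-streamline median, per-edge mean of medians.
* **Caliber filter**: pooled across all subjects and sessions; the
  threshold is the caliber of the $\lceil 0.2 n\rceil$-th largest
  pooled edge and ties at the threshold are kept (the quantile is an
  order statistic with lower interpolation). **Consensus filter**:
  presence in $\lceil 0.5\,n_\mathrm{subjects}\rceil$ subjects —
  ceiling chosen to disambiguate odd cohort sizes.
* **Endpoint assignment**: containing voxel label, else nearest labeled
  voxel center within 2 mm (the gray-matter interface cropping of the
  in-vivo pipeline has no phantom equivalent); undirected edges stored
  as (min, max).
* **FA** is fit log-linearly on shells with $b \le 1000$ (tensor
  validity); thresholds are exposed (0.8 calibration, 0.7 single-fiber
  ROI defaults).
* **Statistics.** ICC is ICC(2,1) — two-way random effects, absolute
  agreement — the natural scan-rescan convention. Bland–Altman
  differences are percentages of the pairwise mean. Correlations are
  Pearson. The mixed model `g ~ caliber + length + (1 + length |
  subject)` is fit by REML; a singular random-effects covariance falls
  back to a random intercept (flagged). The reported adjusted $R^2$ is
  the *marginal* (fixed-effects) one — the conditional variant is
  ambiguous for the "variance explained" question asked here — with the
  usual small-sample adjustment for two predictors.
* **Calibration on phantoms** uses the phantom's analytic voxel-wise
  ICVF grid (the package replaces voxel-wise NODDI fitting with this
  comparator); the COMMIT-derived ICVF map from `fit_filtering()` can be
  passed to `compute_alpha_calib()` instead, at the cost of an extra
  whole-tractogram solve. The two differ by an
  $\mathrm{ISOVF}\cdot\mathrm{MVF}$ cross-term in the denominator
  convention, about 1% here — the same order as the in-vivo discrepancy
  between the two calibration routes.
* **g maps** store NaN (not 0) where $\mathrm{AVF}+\mathrm{MVF}=0$, so
  empty voxels can never silently enter a mean.

## Known limitations

* Per-streamline (as opposed to per-bundle) CSAs are only identifiable
  up to the redundancy of the tractogram; an isolated streamline is
  recovered to $10^{-6}$ relative, but duplicates share their bundle's
  volume in a solver-dependent way.
* Resolution mismatch between DWI and the myelin map (the in-vivo
  pipeline upsamples DWI before the final solve) is out of scope; all
  phantom grids share one resolution, and the handling is parameterized
  only through the affine.
* Diffusivities are fixed, not estimated; compartment T2 differences
  are ignored (signal fractions treated as volume fractions).
* The cohort statistics reproduce conventions, not the human cohort
  values, which depend on a real scan-rescan dataset.
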