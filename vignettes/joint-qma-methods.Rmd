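---
title: "Automated joint alignment, subdivision and morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated joint alignment, subdivision and morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jqma)
```

## The problem

Three-dimensional morphometry of small-animal knee joints (joint space
width and volume, contact behaviour under virtual loading, the femorotibial
centre-of-mass vector) is highly sensitive to two preprocessing steps that
are traditionally manual: putting every scan into a *common orientation*
(tibial long axis vertical, medial–lateral axis horizontal) and splitting
the joint into its medial and lateral compartments. `jqma` automates both
steps for segmented, binarised microCT components (femur, tibia, and their
cartilage masks), and provides the downstream metrics and the
reproducibility statistics used to judge them. The same configuration is
intended to work across animal models of very different physical scale
(rat-sized joints of ~8 mm tibial width at 10 µm voxels, rabbit-sized
joints of ~19 mm at 18 µm), which is what makes the approach *model
invariant*: nothing in the pipeline is tuned to a particular resolution.

## Alignment: a truncated spherical-harmonic form plus PCA

The tibia's boundary surface is extracted as a watertight triangle mesh and
parameterized on the unit sphere, so each vertex carries spherical
coordinates $(\theta, \varphi)$. The three coordinate functions of the
surface are then expanded in spherical harmonics
$Y_l^m(\theta,\varphi)$ with the orthonormal normalisation
$\sqrt{\tfrac{2l+1}{4\pi}\tfrac{(l-m)!}{(l+m)!}}\,P_l^m(\cos\theta)e^{im\varphi}$,
and the coefficient vectors $c_l^m \in \mathbb{R}^3$ are obtained by linear
least squares on the vertex samples. Internally a real (cosine/sine) basis
is used; the complex basis and its conjugation symmetry are available for
conformance checks. The normal-equation form
$c = (z^\top z)^{-1}z^\top v$ is solved through a QR decomposition — on
well-conditioned systems this is the same solution to machine precision,
and it degrades gracefully when the parameterization is poor.

Truncating the expansion at a low degree gives the bone's *basic form*: a
smooth blob that keeps the plate-like proportions of the proximal tibia but
suppresses surface detail such as osteophytes. Principal component analysis
of that form (vertices of the reconstruction on a regular
$(\theta,\varphi)$ grid, weighted by exact quadrature weights so polar
oversampling does not bias the covariance) yields the three anatomical
axes: the smallest principal component is the vertical axis, the
second-smallest the medial–lateral axis. One rigid transform maps these to
$z$ and $x$, re-centres the tibial centre of mass at the world origin, and
is applied identically to all four joint components (cubic B-spline
interpolation with re-binarisation at 0.5), preserving their relative pose.

Two fitting degrees matter. The default fitting degree is $L = 10$; the
pose is estimated from the truncation to $L = 5$ — low enough to suppress
osteophyte-scale detail, high enough to keep the plate-like proportions —
the degree at which centre-of-mass reproducibility peaks in degree sweeps.
`sweep_degree()` runs that parametric study on any set of repeat scans, so
the choice can be re-checked for a new anatomy.

### Sign disambiguation

Eigenvectors are sign-ambiguous, so two anatomical facts fix the signs:

* **vertical** — the bone's long tail (the shaft) points down: the third
  moment of the solid bone's vertical coordinate must be negative;
* **medial–lateral** — the wider (medial) plateau half lies on $-x$: the
  third moment of the ML coordinate must be negative, mirrored for right
  limbs by the `limb_side` flag so medial is *always* on $-x$ afterwards.

An earlier candidate policy — comparing mean cross-sectional areas of the
extreme top versus bottom z-slices — fails on realistic shapes because the
intercondylar tubercles rise above the plateau rim, so the topmost slices
are the narrow tubercle caps rather than the wide plateau. Third moments of
the whole solid are insensitive to that.

The PCA conditioning measure $(\lambda_2-\lambda_3)/\lambda_1$ guards
against ill-posed orientations; below 0.02 the alignment aborts with a
diagnostic rather than silently mis-aligning.

### Spherical parameterization

Two methods are provided. `"radial"` projects along rays from the
volumetric centroid; it is exact for star-shaped surfaces (checked: no
back-facing triangles from the centroid, with a 1 % tolerance for
voxelisation staircase artefacts) and is the default. `"area"` starts from
the radial map and reduces per-triangle area distortion by gradient descent
on the squared relative area mismatch (chord-area surrogate, exact
triangle-area gradients, backtracking line search that only accepts
distortion-reducing steps; defaults `tol = 1e-4`, `max_iter = 200`). The
degree-5 form consumed by the alignment is insensitive to residual area
distortion — the rotation-recovery tests pass with the radial map — so the
relaxation is an option for strongly non-spherical real anatomies rather
than a requirement.

## Subdivision: persistence watershedding of the plateau profile

After alignment, a topographic map of the tibia records the highest
foreground z per $(x, y)$ column. Collapsing the map along the
anterior–posterior axis (default aggregator: `max`, preserving the
tubercle peaks; `mean` is available) gives a 1D height profile along the
medial–lateral axis. The profile is cropped to the central fraction of its
footprint (default 0.5) so that marginal features such as osteophytes
cannot masquerade as landmarks, and affinely rescaled to $[0,1]$ — the
rescale ("boost") does not affect persistence ranking.

1D sublevel-set persistence pairs each local minimum with the maximum at
which its component merges into an older one. The sample domain is treated
as a closed path — both endpoints are adjacent to the background — so the
surviving global minimum pairs with the global maximum, persistences are
shift invariant, and the pairs of one signal have disjoint minima and
disjoint maxima. Equal values are ordered by leftmost index. The two most
persistent pairs carry the two tubercle peaks as their maxima, and the
dividing point is the minimum among them that lies *between* those peaks:
generically this is the second pair's minimum (the global pair's minimum
sits at the object margin), but the rule stays anchored to the
intercondylar valley in the rare situation where surface roughness pushes
the valley below the cropped margins and the valley becomes the global
minimum. Because heights are voxel-quantized the valley floor is a run of
exactly tied samples; the reported coordinate is the centre of that run
(the leftmost-sample convention would carry a systematic bias of several
voxels toward one side). Every mask is then partitioned at the plane
$x = x_{divide}$, voxel centres deciding side membership; with the
alignment's sign convention the medial compartment is the $-x$ side.

## Joint QMA metrics

* **Centre-of-mass vector** — from the tibial to the femoral centre of
  mass; angles $\alpha, \beta, \gamma$ to the $x, y, z$ axes satisfy
  $\cos^2\alpha+\cos^2\beta+\cos^2\gamma = 1$.
* **Contact area under virtual loading** — the tibial composite (bone +
  cartilage) is shifted up the $z$ axis in voxel steps; the contact area at
  displacement $d$ is the $xy$-projected area of the interface where the
  composites touch or overlap. Binary voxel surfaces *touch* when their
  voxel runs become adjacent, so the interface at a displacement of $k$
  voxels is the overlap after shifting $k+1$ — this makes the
  parallel-plate case exact ($\chi$ equals the physical gap). $\chi$ is the
  displacement at first contact (reported in mm); $m$ is the least-squares
  slope of area versus displacement (mm²/mm; the displacement axis is
  physical, not steps) over the window from the last zero-area sample up to
  contact of half the shared footprint.
* **Joint space metrics (SPECTRA-style)** — the joint space mask holds the
  background voxels strictly between the highest tibial and lowest femoral
  voxel of each shared column. Local thickness follows the
  largest-inscribed-sphere definition; the spheres are centred in the joint
  space and bounded only by bone (a sphere may overhang the open lateral
  margin into air but not into bone), so the width measures bone-to-bone
  distance even at the compartment edge. JSW is the volume-weighted mean
  thickness; JSW.min/JSW.max are taken after discarding the lowest 0.1
  percentile of the map (single-voxel artefact guard, configurable);
  JSV is voxel count times voxel volume. Joint space metrics use the bone
  masks; the contact metrics use the bone + cartilage composites.

Columns at vertical walls of the masks can produce thin slivers in the
joint-space mask whose local thickness is small; they make the *extremes*
(JSW.min in particular) less stable than the mean — consistent with the
published observation that JSW.max is not reliable enough for analysis,
and the reason the end-to-end reproducibility claim covers JSW and JSV but
not the extremes.

## Reproducibility statistics

`icc_consistency()` implements the two-way (subjects × repeats) consistency
ICC for the average of $k$ measurements, ICC(C,k) =
(MS$_{rows}$ − MS$_{error}$)/MS$_{rows}$; the consistency formula is
identical under two-way random and mixed models, so that distinction is
immaterial. Confidence intervals come from the F distribution of
MS$_{rows}$/MS$_{error}$; their ~95 % coverage is verified by simulation
against known variance components. Qualitative bands: above 0.75 excellent,
0.6–0.75 good, 0.40–0.60 fair, below 0.40 poor (the boundary 0.75 itself is
assigned to "good"; negative estimates are "poor"). Precision errors follow
the densitometric convention: PE(SD) is the RMS of per-subject standard
deviations over repeats, PE(%CV) the RMS of per-subject coefficients of
variation × 100. RMSE/NRMSE compare against a designated reference series.
Subjects with missing repeats are dropped per metric with a logged count.

## The phantom test bed

Because the original animal scans are not redistributable, every stage is
validated on synthetic joints with known ground truth
(`phantom_spec()`, `make_phantom_joint()`, `make_repeat_scans()`,
`sample_phantom_population()`). The generator voxelises implicit solids
directly in the posed frame (coordinates are pulled back through the
inverse pose), so the stored pose, dividing point, gap field and
centre-of-mass vector are exact, with no resampling error.

Geometry (rat preset; the rabbit preset scales all lengths by
19.10/8.09 and uses 18 µm default voxels):

* plateau: superellipse footprint, ML width 8.09 mm (the published cohort
  mean; between-subject SD 0.62 mm in `sample_phantom_population()`),
  AP depth 9.3 mm — AP exceeds ML, as with the anterior tibial tuberosity,
  which fixes the principal-variance ordering (AP > ML > vertical) —
  height 3.0 mm (an epiphyseal crop is a flat plate, not a long bone), a
  gentle dome (0.35 mm), and a 5 % wider medial half;
* intercondylar tubercles: two *conical* bumps (prominence ≈ 0.86/0.74 mm,
  radius 0.95 mm at ∓0.78 mm) combined by `max()`, so their flanks cross
  in a V-groove — a Gaussian-bump eminence has a flat valley whose
  position is not well-defined at the voxel level;
* femur: two condylar lobes whose lower surfaces sit `gap` (0.56/0.53 mm
  medial/lateral) above the plateau and curve away quadratically
  (effective radius 4 mm), cleared of the eminence by an intercondylar
  notch and joined by a bridge; an offset of the bridge varies the
  centre of mass between subjects;
* cartilage: 0.11 mm uniform shells on the apposing surfaces (at coarse
  test voxels the voxelised sheet is clamped to one voxel so it cannot
  fragment), leaving a cartilage-to-cartilage clearance of ≈ 0.3 mm,
  consistent with published first-contact distances;
* repeat scans: bounded rigid jitter (default ±10°, ±20 voxels) and a
  fresh roughness realisation per repeat; roughness is a dense correlated
  random field (smoothed white noise, correlation length one third of a
  tubercle radius, exact RMS normalisation), emulating the residual
  surface texture of filtered, segmented microCT.

What the phantoms deliberately do **not** model: trabecular texture, scan
artefacts (beam hardening, rings), contrast-agent effects, segmentation
errors beyond smooth surface roughness, and anatomical asymmetries beyond
the parameterised ones. Passing the phantom suite therefore demonstrates
the pipeline's geometric and statistical correctness, not its performance
on any particular scanner's output.

## Problem sizes and numerical choices

The test suite and the acceptance script run the phantoms at coarser voxel
sizes than the original scans so that the whole validation executes on a
single CPU in minutes: 80 µm (rat) / 180 µm (rabbit) for rotation-recovery
and subdivision studies, 120 µm for the 21-subject × 4-repeat end-to-end
reproducibility study. Geometry is unchanged — only the sampling is
coarser — and all voxel-denominated tolerances refer to these voxel sizes.

Other fixed numerical choices: surface extraction smooths the binary
indicator with a 0.7-voxel Gaussian before iso-surfacing at 0.5 (falling
back to the raw indicator for objects small enough to be erased) and
applies 10 Taubin passes (λ = 0.5, µ = −0.53); these remove the
staircase bias in surface area (a 20-voxel digital ball comes out within
~1 % of its analytic area) without shrinking the object. Resampling uses
prefiltered cubic B-splines, so the identity transform is voxel-exact.
Quadrature on the regular $(\theta,\varphi)$ grid uses
Driscoll–Healy-type weights (`theta_quadrature_weights()`), which make the
basis Gram matrix exact to machine precision — naive
$\sin\theta\,\Delta\theta$ midpoint weights leave ~10⁻³ errors that break
the rotation equivariance of the truncated form. Least-squares fits cap
the vertex count at 20 000 by regular subsampling (the system is heavily
overdetermined). The fitting degree/vertex-budget precondition
$n_{vert}\ge(L+1)^2$, rank checks, and condition-number diagnostics are
enforced rather than assumed.

## Known limitations

* The radial parameterization requires star-shaped tibiae; strongly
  non-star anatomies (e.g. VOIs cropped through the medullary canal leaving
  convex ends) need the `"area"` method or manual closing/smoothing before
  the pipeline, and genus ≠ 0 inputs are rejected outright. A morphological
  closing radius is deliberately exposed as preprocessing left to the user
  rather than automated.
* The dividing-point detector locates the valley to one voxel for surface
  roughness up to roughly 15 % of the valley's topographic prominence
  (peak-above-saddle height). Beyond that the valley of the *profile
  itself* moves by more than a voxel — the flank slopes are below unity,
  so roughness of amplitude σ displaces the observed valley by at least
  σ/slope regardless of the estimator. With roughness drawn up to 20 % of
  the full tubercle height, a few cases in fifty land 1–2 voxels off.
* χ is quantized to the contact step (default one voxel); discriminating
  between-subject differences smaller than a voxel requires finer voxels,
  exactly as in the original resolution-rich setting.
* JSW.min and JSW.max inherit sliver sensitivity from the strict
  between-bones column rule (see above) and are reported but not part of
  the headline reproducibility claim.
* 21 joints from 11 animals are treated as independent subjects in the
  reproducibility statistics, replicating the original analysis; a
  clustered model is out of scope.
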