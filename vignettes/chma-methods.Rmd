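---
title: "Canonical holistic morphometric analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical holistic morphometric analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the synthetic
test bed does and does not demonstrate about real data. Code chunks are
illustrative and not evaluated when the package is built; every empirical
number quoted here is computed by the test suite or by
`scripts/acceptance.R`, not asserted from memory.

## The problem and the pipeline

Trabecular bone remodels under load, so the spatial distribution of bone
volume fraction (BV/TV) inside, say, a metacarpal head records something
about habitual joint use. Comparing that distribution *across* individuals
requires anatomical correspondence below the whole-bone level. `chma`
establishes correspondence the landmark-free way: build one average
("canonical") bone image for the sample, mesh it once, and carry that single
mesh onto every specimen through the registration transforms. After that,
element `k` is the same place in everyone, and per-element statistics are
meaningful.

The pipeline (`run_chma()`) is: compartment masking → canonical bone
(statistical deformation model) → per-specimen registration → averaged
trabecular mask in canonical space → canonical tetrahedral mesh → mesh
morphing → spherical-ROI BV/TV mapping on the original images → rBV/TV →
element-wise statistics.

## Image model and coordinate conventions

A `masked_image` couples a scalar volume (binary bone, or grey) with a
whole-bone label mask, voxel spacing and world origin. World coordinates
follow the voxel-centre convention of mainstream medical-imaging toolkits:
`position = origin + index * spacing`, 0-based indices, axis-aligned
volumes. Grey values are interpolated linearly and label masks with
nearest-neighbour lookup everywhere in the package — linear interpolation of
labels would mix them. Binary inputs resampled to a coarser grid therefore
become fractional occupancy images; this is deliberate, since the
normalised cross-correlation (NCC) registration works better on these
smooth "density" images than on hard binaries.

All transforms map **fixed (canonical) space into moving (individual)
space**, the standard resampling convention. The same map that pulls a
moving image onto the canonical grid pushes canonical mesh vertices onto
the individual bone — which is why registration output can be used for
morphing without inversion.

## Compartment masking

`fill_masks()` separates the trabecular from the cortical compartment of a
binary bone image: morphological closing (ball radius `closing_radius`,
default 5 voxels) seals surface pores, cavity filling yields the periosteal
volume, and erosion by `shell_offset` (default 2 voxels) places the
endosteal boundary. The trabecular mask is the *filled* interior volume —
pores of the network are part of the trabecular volume, as they must be for
BV/TV denominators. Both radii are physical (mm) and honour anisotropic
spacing; morphology is implemented with FFT convolutions against ball
kernels, which is exact for binary inputs after integer thresholding.
Whether the trabecular mask should abut the endosteal surface or leave a
buffer is a judgement call; it is governed entirely by `shell_offset` and
exposed in the pipeline config. Pre-masked data can bypass this stage via
`compartment_masks()`.

## Registration

**Similarity stage.** `register_similarity()` optimises rotation (rotation
vector), log-scale and translation about the fixed-image centre with R's
conjugate-gradient line-search optimiser, over a two-level coarse-to-fine
schedule. NCC has a narrow capture range, so initialisation matters:
candidate starts are built from mask centroids, mask-volume ratio
(`scale0 = (V_m/V_f)^(1/3)`) and principal axes (four sign-consistent axis
pairings; skipped when the shape is too isotropic for stable axes,
eigenvalue ratio < 1.2), and the best-scoring candidate seeds the
optimiser. The metric is evaluated over the union of the dilated fixed mask
and the dilated moving mask mapped through the initial transform — computed
once per call, not re-warped every iteration, which keeps the objective
smooth; pure background would otherwise dominate the correlation.

**Free-form stage.** `register_bspline()` refines with a cubic B-spline
free-form deformation. The control grid spans the fixed image domain with
`round(extent/spacing)` intervals per axis (minimum 1) — the counts that
are conventionally reported for a grid — and the *actual* control spacing
is `extent/n`, so the grid always covers the domain exactly. Optimisation
is L-BFGS-B with analytic gradients (the NCC gradient chains through the
interpolated moving-image gradient and the tensor-product B-spline basis;
both directions are evaluated as mode products against per-axis basis
matrices, which is what makes a pure-R implementation fast). There is no
explicit regularisation term; smoothness is governed by the grid spacing,
plus box bounds on the control displacements (`max_disp_factor`, default
0.4 × spacing). The bounds matter: corner control points far from the
evaluation region feel almost no gradient, and without bounds the optimiser
can park them at large displacements that later break transform inversion.
Bounding control displacements is the lightweight member of the standard
family of FFD controls.

The total per-specimen map is `T(x) = S(x + u(x))`: the deformation acts in
the canonical domain, the similarity then carries the point into the
individual space, i.e. `compose_transforms(bspline, similarity)`. The
alternative order (deformation in individual space) would give every
specimen a differently-placed control grid and make the population's
control-point displacements un-averageable; with the shared canonical-domain
grid, averaging is a per-point mean. `compose_transforms(a, b)` itself is
order-transparent: the composite applies `a` first, then `b`.

Because both transform families are smooth over the whole domain,
transforms estimated on rescaled images remain valid at full resolution;
the resolution-transfer property (Dice change < 0.02 between evaluation at
low and full resolution) is asserted in the tests.

## The statistical deformation model

`build_canonical()` iterates: similarity-register all → average (arithmetic
means for translation and scale, quaternion averaging — the principal
eigenvector of `Σ w q qᵀ`, sign-invariant — for rotation; a fixed common
rotation centre makes this decomposition well-defined) → apply the
*inverse* average to the reference → similarity + B-spline register all →
average the transformed images and the control displacements → apply the
inverted average B-spline → new reference. Two iterations are the default;
convergence is quantified by Dice/MSD/Hausdorff between consecutive
references, recorded per iteration. Rigid-body drift between iterations is
not corrected, only reported — it inflates the between-iteration surface
distance without changing shape.

Open choices made here:

* **Averaged mask** = voxels where ≥ 50% of the transformed masks are bone
  (majority vote keeps topology reasonable; a mean-then-threshold of
  fractional masks at 0.5 is equivalent for binary inputs).
* **B-spline inversion** is a damped fixed-point iteration
  `v ← v + 0.7(−u(x + v) − v)` whose iterates are refitted to the control
  grid by per-axis least squares on a quarter-spacing sampling of the valid
  spline domain. Outside its valid support the displacement field is
  extended as a constant; together with the displacement bounds this keeps
  the iteration contractive. The composition residual `|T(T⁻¹(x)) − x|` is
  checked on a probe grid (tolerance 0.1 mm by default, half a rescaled
  voxel inside the model loop) and reported; non-convergence warns rather
  than fails.
* **Cold start each iteration**: iteration k+1 does not reuse iteration-k
  transforms as initialisation (simpler, and the centroid/axes
  initialisation makes warm starts unnecessary at these problem sizes).

## Meshing and morphing

`mesh_from_mask()` is a lattice mesher: the mask is covered with a regular
cube grid and each cell whose centre lies inside the mask is split into six
conforming, positively oriented tetrahedra (Kuhn/Freudenthal subdivision).
The cube side is `edge_length/1.2`, chosen because a Kuhn cell's edges are
`{h, h√2, h√3}` and the shared-edge median then lands near the requested
characteristic edge length (within 30%, asserted). The mesh volume tracks
the mask volume within a few percent for smooth shapes resolved by several
cells. Any mesher meeting those postconditions would be conformant; the
lattice mesher is deterministic, dependency-free and exactly reproducible.

`morph_mesh()` maps vertices through the per-specimen transform and never
touches connectivity, so the population's meshes are isotopological by
construction (asserted bit-identically in the pipeline tests). Inverted
elements are counted, not repaired — remeshing would destroy the element
homology that the whole method exists to provide, so excessive distortion
must be prevented upstream (large grid spacing, displacement bounds).
Quality metrics: tet-collapse normalises `min_i h_i/√A_i` by the
regular-tetrahedron value `2√2·3^(−3/4)` (so regular = 1, collapsed = 0);
volume-skew compares the element volume against the equilateral tetrahedron
sharing its circumradius (equilateral = 0, degenerate = 1, coplanar
vertices = 1 by convention); aspect ratio is the longest edge over the
minimum height — its definition varies across the FE literature, it is used
for reporting only, with the conventional acceptance guideline of < 5% of
elements above 5.

## BV/TV mapping (HMA)

The background grid is isotropic with spacing `r` and covers the trabecular
mask bounding box padded by `r`; each vertex carries the bone fraction
among voxel centres inside a sphere of radius `r` — the sphere diameter is
twice the grid spacing, so neighbouring samples overlap, the discretised
analogue of overlapping homogenisation windows. The 2.5 mm/5 mm default
pairing follows the homogenisation scale for trabecular bone. Two
conventions were left open by the method description and resolved as:

* **Denominator**: voxels outside the trabecular mask are excluded from the
  sphere's total (`denominator = "mask"`). Including them would dilute
  BV/TV wherever a sphere clips the endosteal boundary — an edge artefact,
  not signal. The `"full"` convention is available as a switch.
* **Missing vertices** (fewer than `min_voxels` mask voxels in reach, default
  10) are filled from the nearest defined vertex before interpolation, and
  the fill count is recorded; dropping affected elements is the
  alternative when a population matrix without imputation is wanted.

Element values are trilinear interpolations of the eight surrounding
vertices at the element centroid — evaluated in *individual* space on the
*original-resolution* image with the morphed mesh. Transforming the images
instead would interpolate, and thereby distort, the microstructure that is
being measured; this is the single most important invariant of the
pipeline. rBV/TV divides by the specimen's unweighted mean over elements
(volume-weighting would couple the normalisation to mesh grading; the
unweighted mean matches the convention of normalising a sample's field by
its mean value), making fields comparable across specimens of different
overall density; the output mean is exactly 1.

## Statistics

Element-wise pooled-variance two-sample t statistics (Welch is available as
a design alternative but pooled variance is the default, matching the
"independent samples t-test" convention); zero pooled variance yields t = 0
for equal means and a signed infinity otherwise, which propagates sensibly
through thresholding. Family-wise error is controlled by the permutation
max-|t| procedure: the null distribution of the maximum absolute statistic
over label permutations gives the critical value as its `1 − α` empirical
quantile (inverse-ECDF order statistic, observed labelling included among
the permutations — the standard construction whose validity the Monte-Carlo
test checks). When the number of distinct label assignments is at most
`n_perm` they are enumerated exhaustively and the result is seed-free.

The `1.5`-pooled-SD power figure sometimes quoted for such designs belongs
to the *uncorrected* per-element test (power ≈ 0.88 at n = 10 per group);
under max-|t| FWER control at a few hundred elements the same effect has
per-element power below 0.2. The test suite asserts the uncorrected power
figure and, separately, that FWER-flagged elements concentrate in the
planted region; the end-to-end acceptance run plants a stronger image-level
effect and demonstrates majority detection after FWER control.

PCA is the SVD of the column-centred specimen-by-element matrix, scores
signed so each component's largest-magnitude loading is positive.
Percentile thresholding marks elements strictly above the
linear-interpolation quantile (R type 7) — the convention matters at the
80th percentile of small fields and is therefore documented and tested.

## The synthetic test bed

`make_bone()` builds a stylised bone: a tri-axial ellipsoid
(default semi-axes 7 × 9 × 13 mm — metacarpal-like, deliberately
anisotropic in cross-section so that rotation is identifiable by
registration) perturbed by a smooth random field, a cortical shell (1.5 mm),
and an interior textured by thresholded smoothed white noise whose local
fill fraction follows a prescribed field `p(x)` exactly in distribution
(the noise is rank-transformed to uniform before thresholding at `p`). The
texture correlation length defaults to 0.25 mm — below the voxel size — so
that realised fill matches `p` within 0.02 on homogenisation-scale windows;
real rod-and-plate architecture is explicitly *not* emulated.
`make_population()` warps one template per specimen (similarity: scale
0.9–1.1, rotation ≤ 15°, translation ≤ `max_trans_mm`; plus a smooth random
B-spline warp) and textures each specimen independently; group effects
multiply `p` inside a stored spherical region of the template frame. All
generation is bit-reproducible from the seed.

What passing tests on this bed shows: the geometry chain (registration →
morphing → sphere sampling → interpolation → statistics) recovers known
truth at the stated tolerances, and the error-control machinery is valid.
What it does not show: robustness to scanner noise, beam hardening,
segmentation error, taphonomic damage, or genuinely trabecular (rod/plate,
anisotropic) microarchitecture — real-data performance on those axes is
outside what synthetic phantoms can certify.

## Problem sizes and tolerances used by the checks

The test suite and acceptance script run at desk scale, chosen so the full
suite completes in a few minutes on one CPU: bones of ~48³–84³ voxels at
0.5 mm, registration at 1–2 mm (rescale factors 2–4), B-spline grids of
8–10 mm, meshes of ~800–3500 elements, populations of 4–12 specimens, and
the FWER null simulation at its full stated size (two groups of 10, 500
elements, 2000 permutations, 500 replicates). Key tolerances: similarity
recovery within 0.5 rescaled voxel / 2° / 2% scale; composed registration
at least halves the surface distance of a known ≤ 2 mm warp; B-spline
inversion residual < 0.1 mm; BV/TV sphere values match exhaustive
enumeration exactly; trilinear interpolation reproduces linear fields to
1e-9; the canonical model's between-iteration surface distance decreases
from iteration 1 to 2 on a six-bone population.

## Known limitations

* Axis-aligned geometry only (no oblique direction cosines in volume I/O).
* The lattice mesher produces structured meshes; boundary staircase effects
  make the outermost element layer noisier than a boundary-fitted mesh
  would be.
* No fabric-tensor/anisotropy morphometry, no cortical-thickness mapping,
  no finite-element export beyond VTK, no random-field-theory thresholds —
  all deliberately out of scope.
* The B-spline inversion assumes the deformation is small relative to the
  grid spacing (diffeomorphic in practice); it warns, with the measured
  residual, when that assumption fails.
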