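# chma — canonical holistic morphometric analysis of trabecular bone

`chma` compares the internal architecture of bones across individuals and
species at homologous locations, without landmarks and without hand-placed
regions of interest. It is aimed at biological anthropologists,
morphometricians and bone biomechanics researchers working with segmented
micro-CT scans.

The problem: trabecular bone adapts to loading, so its local bone volume
fraction (BV/TV) carries behavioural and functional signal — but "the same
spot" is hard to define across differently shaped bones. `chma` solves this
by building a **canonical bone** for the whole sample and giving every
specimen the **same tetrahedral mesh**, so that element *k* means the same
anatomical location in every individual.

## The method

1. **Canonical bone (statistical deformation model).** All binary bone
   images are rescaled to a registration-friendly voxel size (e.g. 10×) and
   registered to a reference with a similarity transform
   (`y = sR(x − c) + c + t`, optimised by negative normalised
   cross-correlation), then with a cubic B-spline free-form deformation on a
   control grid spanning the image (interval counts
   `round(extent / spacing)`, e.g. 5 × 5 × 13 at 4 mm for a
   20.2 × 20.4 × 53.4 mm image). Transforms are averaged — translations and
   scales arithmetically, rotations by quaternion averaging, control-point
   displacements per point — and the inverted averages pull the reference to
   the population mean shape. One to two iterations suffice.
2. **Isotopological meshes.** The average trabecular mask in canonical space
   is meshed once with linear tetrahedra; the per-specimen transforms then
   move only the mesh *vertices* onto each bone. Element connectivity is
   shared by construction; element quality is tracked with tet-collapse
   (1 = regular, 0 = collapsed) and volume-skew (0 = equilateral,
   1 = degenerate).
3. **Holistic morphometric analysis.** On each *original-resolution* image,
   BV/TV is evaluated in overlapping spherical ROIs centred on a regular
   background grid (2.5 mm spacing, hence 5 mm sphere diameter) and
   interpolated tri-linearly at the element centroids. Each specimen's field
   is divided by its own mean (rBV/TV, mean 1) to remove size-of-signal
   differences between taxa.
4. **Element-wise statistics.** Pooled-variance t tests at every element,
   with a max-|t| permutation threshold controlling the family-wise error
   rate at α = 0.05, plus PCA of the specimen-by-element matrix and
   percentile thresholding of mean fields (e.g. the 80th percentile to
   extract high-density structures).

Because no micro-CT populations ship with the package, a synthetic-bone
generator (`make_bone()`, `make_population()`) produces stylised bones with
known deformations, a known BV/TV field and a known planted group effect, so
the whole pipeline is testable against ground truth.

## Worked example

Ten synthetic bones in two groups; group B has BV/TV raised by 100% inside a
stored 4.5 mm-radius region. The full pipeline — masking, canonical bone,
registration, meshing, morphing, BV/TV mapping, statistics:

```r
library(chma)

pop <- make_population(n_per_group = 5, groups = c("A", "B"), effect_size = 1.0,
                       warp_scale_mm = 1, effect_radius = 4.5,
                       field = bvtv_field_params(base = 0.3, slope = c(0, 0, 0)),
                       seed = 5)
cfg <- chma_config(rescale_factor = 4, bspline_grid_spacing = 10,
                   sdm_iterations = 2, mesh_edge_length = 3,
                   hma_grid_spacing = 2.5, n_perm = 2000, seed = 9,
                   shell_offset = 1.5)
run <- run_chma(pop$images, pop$groups, cfg, out_dir = "chma_out")
print(run)
#> chma_run: 10 specimens, groups: A, B
#>   canonical mesh: 768 elements
#>   mean registration Dice: 0.9256
#>    A_vs_B : 99 significant elements
generics::glance(run$stats$A_vs_B)
#>     t_crit alpha n_perm exhaustive n_elements n_significant
#> 1 6.517922  0.05    252       TRUE        768            99
round(100 * run$pca$explained[1:2], 1)
#> [1] 60.6  9.6
```

Reading the numbers: every specimen was registered onto the canonical bone
with mean Dice overlap 0.93; the shared mesh has 768 tetrahedra. The
permutation null (252 exhaustive relabellings of 5 vs 5) puts the
family-wise critical value at |t| ≥ 6.52, and 99 elements — concentrated in
the planted region, as `run$stats$A_vs_B` shows element by element — differ
significantly between the groups. The first principal component, separating
the groups, carries 60.6% of the rBV/TV variance. `chma_out/` holds the
canonical image, transforms, meshes with rBV/TV cell data, the population
matrix, statistics tables and a JSONL run log.

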