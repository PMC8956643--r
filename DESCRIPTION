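Package: chma
Title: Canonical Holistic Morphometric Analysis of Trabecular Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a canonical bone image from a population of segmented
    micro-CT scans with a statistical deformation model (iterated similarity
    and cubic B-spline free-form registration with transform and image
    averaging), generates one canonical tetrahedral mesh and morphs it onto
    every individual so that all specimens share element-level homology, maps
    bone volume fraction (BV/TV) onto mesh elements through overlapping
    spherical sampling regions on a regular background grid, and compares
    groups element-wise with permutation-based family-wise error rate control.
    Includes trabecular/cortical compartment masking, image overlap and
    surface-distance metrics, mesh quality metrics, a synthetic bone-population
    generator with known ground truth, MetaImage/NIfTI volume I/O and VTK mesh
    output, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    RNifti,
    jsonlite,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
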