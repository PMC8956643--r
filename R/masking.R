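#' Separate trabecular and cortical compartments ("fill" masking)
#'
#' Splits a binary bone image into a trabecular volume mask (the filled
#' interior, pores of the trabecular network included) and a cortical mask
#' (the outer shell), in the spirit of fill-type compartment separation:
#' the bone image is morphologically closed with a ball of radius
#' `closing_radius` to seal surface pores, internal cavities are filled to
#' obtain the periosteal volume, and that volume is eroded by `shell_offset`
#' to place the endosteal boundary; everything between the filled surface and
#' the eroded volume is cortical, the eroded interior is trabecular.
#'
#' @param img a binary [masked_image].
#' @param closing_radius ball radius in mm for the closing step; default 5
#'   voxels.
#' @param shell_offset erosion depth in mm defining the cortical shell
#'   thickness retained around the trabecular volume; default 2 voxels.
#' @return An object of class `compartment_masks`: list with integer arrays
#'   `trabecular` and `cortical` (disjoint, both subsets of the whole-bone
#'   mask) and `params`.
#' @export
fill_masks <- function(img, closing_radius = NULL, shell_offset = NULL) {
  stopifnot(inherits(img, "masked_image"))
  sp <- img$spacing
  closing_radius <- closing_radius %||% (5 * min(sp))
  shell_offset <- shell_offset %||% (2 * min(sp))
  extent <- dim(img$values) * sp
  if (closing_radius < 0 || shell_offset < 0) stop("radii must be >= 0")
  if (closing_radius >= min(extent) || shell_offset >= min(extent)) {
    stop("structuring radius exceeds the image extent")
  }
  bone <- img$values > 0.5 & img$mask > 0
  if (!any(bone)) stop("empty bone image")
  closed <- close_binary(bone, closing_radius, sp)
  filled <- fill_holes(closed)
  trab <- if (shell_offset > 0) erode_binary(filled, shell_offset, sp) else filled
  inside_mask <- img$mask > 0
  trab <- trab & inside_mask
  cort <- filled & !trab & inside_mask
  structure(list(
    trabecular = array(as.integer(trab), dim(bone)),
    cortical = array(as.integer(cort), dim(bone)),
    params = list(closing_radius = closing_radius, shell_offset = shell_offset,
                  spacing = sp, origin = img$origin)
  ), class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat("compartment_masks:\n")
  cat("  trabecular voxels:", sum(x$trabecular), "\n")
  cat("  cortical voxels  :", sum(x$cortical), "\n")
  cat("  closing_radius:", x$params$closing_radius, "mm; shell_offset:",
      x$params$shell_offset, "mm\n")
  invisible(x)
}

#' Wrap externally produced compartment masks
#'
#' Case-study inputs may arrive pre-masked; this constructor accepts
#' trabecular/cortical label arrays directly so the pipeline can bypass
#' [fill_masks()].
#'
#' @param trabecular,cortical 3D label arrays (same dimensions, disjoint).
#' @param spacing,origin geometry of the arrays.
#' @export
compartment_masks <- function(trabecular, cortical, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  stopifnot(identical(dim(trabecular), dim(cortical)))
  if (any(trabecular != 0 & cortical != 0)) stop("trabecular and cortical masks overlap")
  structure(list(
    trabecular = array(as.integer(trabecular != 0), dim(trabecular)),
    cortical = array(as.integer(cortical != 0), dim(cortical)),
    params = list(closing_radius = NA_real_, shell_offset = NA_real_,
                  spacing = rep_len(spacing, 3), origin = rep_len(origin, 3))
  ), class = "compartment_masks")
}

#' Write compartment masks as one label volume
#'
#' Labels: 0 background, 1 trabecular, 2 cortical.
#' @param masks a `compartment_masks` object.
#' @param path output volume (`.mha`, `.mhd`, `.nii`, `.nii.gz`).
#' @export
write_compartment_masks <- function(masks, path) {
  lab <- masks$trabecular + 2L * masks$cortical
  write_volume(array(as.numeric(lab), dim(lab)), masks$params$spacing,
               masks$params$origin, path)
}
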