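# Overlap and surface-distance metrics for binary masks, used for
# registration QC and for the convergence diagnostics of the canonical-bone
# model.

mask_of <- function(x) {
  if (inherits(x, "masked_image")) list(arr = x$mask > 0, spacing = x$spacing, origin = x$origin)
  else list(arr = x != 0, spacing = c(1, 1, 1), origin = c(0, 0, 0))
}

#' Dice overlap coefficient
#'
#' `2|A∩B| / (|A|+|B|)` for two binary masks on the same voxel grid. For
#' `masked_image` inputs the whole-bone mask is compared.
#'
#' @param a,b binary 3D arrays or [masked_image]s with identical geometry.
#' @return overlap fraction in \[0, 1\].
#' @export
dice <- function(a, b) {
  ma <- mask_of(a)$arr; mb <- mask_of(b)$arr
  if (!identical(dim(ma), dim(mb))) stop("masks have different dimensions")
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) stop("Dice undefined: both masks are empty")
  2 * sum(ma & mb) / (na + nb)
}

# Boundary voxels: foreground voxels with at least one background
# 6-neighbour (voxels on the array border count as boundary).
boundary_voxels <- function(m) {
  d <- dim(m)
  interior_nb <- array(TRUE, d)
  for (a in 1:3) for (s in c(-1, 1)) interior_nb <- interior_nb & shift1(m, a, s)
  m & !interior_nb
}

# mm coordinates of boundary voxel centres
boundary_points <- function(m, spacing, origin) {
  idx <- which(boundary_voxels(m), arr.ind = TRUE) - 1L
  sweep(sweep(idx, 2, spacing, "*"), 2, origin, "+")
}

# For each row of a, distance to the nearest row of b (chunked to bound
# memory).
nearest_distances <- function(a, b, chunk = 2048L) {
  nb2 <- rowSums(b^2)
  out <- numeric(nrow(a))
  i <- 1L
  while (i <= nrow(a)) {
    j <- min(i + chunk - 1L, nrow(a))
    blk <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), nb2, "+") - 2 * blk %*% t(b)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
    i <- j + 1L
  }
  out
}

#' Surface distances between two binary masks
#'
#' Surfaces are the boundary voxels (foreground voxels with a background
#' 6-neighbour); distances are Euclidean between boundary voxel centres, in
#' mm. The mean surface distance (MSD) is symmetric — the average of the two
#' directed mean distances — and the Hausdorff distance is the larger of the
#' two directed maxima.
#'
#' @param a,b binary 3D arrays or [masked_image]s with identical geometry.
#' @return list with `msd` and `hausdorff`, both in mm.
#' @export
surface_distances <- function(a, b) {
  ga <- mask_of(a); gb <- mask_of(b)
  if (!identical(dim(ga$arr), dim(gb$arr))) stop("masks have different dimensions")
  if (!any(ga$arr) || !any(gb$arr)) stop("surface distances undefined for an empty mask")
  pa <- boundary_points(ga$arr, ga$spacing, ga$origin)
  pb <- boundary_points(gb$arr, gb$spacing, gb$origin)
  dab <- nearest_distances(pa, pb)
  dba <- nearest_distances(pb, pa)
  list(msd = (mean(dab) + mean(dba)) / 2,
       hausdorff = max(max(dab), max(dba)))
}
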