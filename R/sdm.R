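# Statistical deformation model: the canonical bone image is built by
# iteratively registering every specimen to a reference, averaging the
# resulting transforms and images, and pulling the reference toward the
# population mean with the inverted average transforms.

#' Average unit quaternions
#'
#' Rotation averaging as the principal eigenvector of the weighted outer
#' product accumulator `sum(w_i q_i q_i^T)`; invariant to per-input sign
#' flips, with the result sign-fixed to a non-negative scalar part.
#'
#' @param quats list (or 4-column matrix) of unit quaternions (w, x, y, z).
#' @param weights non-negative weights, sum > 0.
#' @return the average unit quaternion.
#' @export
average_quaternions <- function(quats, weights = NULL) {
  if (is.matrix(quats)) quats <- asplit(quats, 1)
  if (length(quats) == 0) stop("need at least one quaternion")
  weights <- weights %||% rep(1, length(quats))
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be non-negative with positive sum")
  acc <- matrix(0, 4, 4)
  for (i in seq_along(quats)) {
    q <- quat_normalize(as.numeric(quats[[i]]))
    acc <- acc + weights[i] * tcrossprod(q)
  }
  ev <- eigen(acc, symmetric = TRUE)
  q <- ev$vectors[, 1]
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

#' Average similarity transforms
#'
#' Arithmetic mean of translations and scales, quaternion averaging of the
#' rotations; all inputs must share the same rotation centre, which is
#' preserved.
#'
#' @param ts list of [similarity_transform]s.
#' @export
average_similarity <- function(ts) {
  stopifnot(length(ts) >= 1)
  ctr <- ts[[1]]$center
  for (t in ts) {
    if (max(abs(t$center - ctr)) > 1e-9) stop("similarity transforms have mismatched centres")
  }
  similarity_transform(
    rotation = average_quaternions(lapply(ts, `[[`, "rotation")),
    scale = mean(vapply(ts, `[[`, numeric(1), "scale")),
    translation = colMeans(do.call(rbind, lapply(ts, `[[`, "translation"))),
    center = ctr)
}

#' Average B-spline transforms
#'
#' Per-control-point arithmetic mean of the displacement vectors; all inputs
#' must share identical grid geometry.
#'
#' @param ts list of [bspline_transform]s.
#' @export
average_bspline <- function(ts) {
  stopifnot(length(ts) >= 1)
  g <- ts[[1]]
  for (t in ts) {
    if (!identical(t$grid_dims, g$grid_dims) ||
        max(abs(t$grid_origin - g$grid_origin)) > 1e-9 ||
        max(abs(t$grid_spacing - g$grid_spacing)) > 1e-9) {
      stop("B-spline transforms have mismatched control grids")
    }
  }
  disp <- Reduce(`+`, lapply(ts, `[[`, "displacements")) / length(ts)
  bspline_transform(g$grid_origin, g$grid_spacing, g$grid_dims, disp)
}

# Least-squares B-spline coefficients reproducing given displacement values
# sampled on the half-spacing grid (denser than collocation at the control
# points, which keeps the representation error of composed fields small).
# The per-axis normal matrices are well conditioned.
half_grid_coords <- function(t, axis) {
  m <- t$grid_dims[axis]
  # sample the valid spline domain only (outside it the field is clamped)
  t$grid_origin[axis] + seq(1, m - 2, by = 0.25) * t$grid_spacing[axis]
}

bspline_fit_values <- function(t, sampler) {
  m <- t$grid_dims
  ax <- lapply(1:3, function(a) half_grid_coords(t, a))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  vals <- sampler(pts)
  B <- lapply(1:3, function(a) {
    bspline_axis_basis(ax[[a]], t$grid_origin[a], t$grid_spacing[a], m[a])
  })
  proj <- lapply(B, function(b) solve(crossprod(b), t(b)))
  out <- array(0, c(m, 3))
  nd <- lengths(ax)
  for (a in 1:3) {
    v <- array(vals[, a], nd)
    v <- ttm3(v, proj[[1]], 1L)
    v <- ttm3(v, proj[[2]], 2L)
    v <- ttm3(v, proj[[3]], 3L)
    out[, , , a] <- v
  }
  out
}

#' Approximate inverse of a B-spline transform
#'
#' Fixed-point iteration on the control grid: the inverse displacement `v`
#' satisfies `v(x) = -u(x + v(x))`; values are iterated at the control-point
#' locations and refitted to B-spline coefficients each pass. Valid when the
#' deformation is small relative to the grid spacing (diffeomorphic in
#' practice).
#'
#' @param t a [bspline_transform].
#' @param tol target composition residual `|T(T^-1(x)) - x|`, mm.
#' @param max_iter iteration cap.
#' @return a [bspline_transform] on the same grid, with attributes
#'   `residual` (max composition residual on a probe grid, mm) and
#'   `converged`.
#' @export
invert_bspline_approx <- function(t, tol = 0.1, max_iter = 50) {
  m <- t$grid_dims
  inv <- bspline_transform(t$grid_origin, t$grid_spacing, m)
  damp <- 0.7   # under-relaxation keeps the iteration contractive
  for (it in seq_len(max_iter)) {
    coef <- bspline_fit_values(t, function(pts) {
      v <- bspline_displacement(inv, pts)
      v + damp * (-bspline_displacement(t, pts + v) - v)
    })
    delta <- max(abs(coef - inv$displacements))
    if (!is.finite(delta)) {
      warning("B-spline inversion diverged (deformation too large for the grid)")
      break
    }
    inv$displacements <- coef
    if (delta < tol / 10) break
  }
  # composition residual on a probe grid spanning the control domain interior
  probe <- as.matrix(expand.grid(
    seq(t$grid_origin[1] + t$grid_spacing[1], by = t$grid_spacing[1] / 2, length.out = 2 * (m[1] - 3) - 1),
    seq(t$grid_origin[2] + t$grid_spacing[2], by = t$grid_spacing[2] / 2, length.out = 2 * (m[2] - 3) - 1),
    seq(t$grid_origin[3] + t$grid_spacing[3], by = t$grid_spacing[3] / 2, length.out = 2 * (m[3] - 3) - 1)))
  back <- transform_points(inv, probe)
  res <- sqrt(rowSums((transform_points(t, back) - probe)^2))
  attr(inv, "residual") <- max(res)
  attr(inv, "converged") <- max(res) < tol
  if (!attr(inv, "converged")) {
    warning("B-spline inversion residual ", signif(max(res), 3), " mm exceeds tol ", tol, " mm")
  }
  inv
}

# Voxelwise mean of transformed images; mask by majority vote (>= 50%).
average_images <- function(imgs, geom) {
  acc_v <- array(0, geom$dim); acc_m <- array(0, geom$dim)
  for (im in imgs) { acc_v <- acc_v + im$values; acc_m <- acc_m + im$mask }
  masked_image(acc_v / length(imgs),
               array(as.integer(acc_m >= length(imgs) / 2), geom$dim),
               spacing = geom$spacing, origin = geom$origin)
}

#' Build the canonical bone image
#'
#' Iterates the statistical deformation model on a population of masked
#' images: (1) similarity-register every (rescaled) image to the current
#' reference; (2) average the similarity transforms and apply the inverse of
#' the average to the reference, moving it to the population mean pose;
#' (3) register every image to the aligned reference with similarity plus
#' B-spline free-form deformation; (4) average the transformed images
#' (voxelwise grey mean, mask majority vote) and the control-point
#' displacements; (5) apply the inverted average B-spline to the averaged
#' image, yielding the new reference. Dice, mean surface distance and
#' Hausdorff distance between consecutive references quantify convergence.
#'
#' @param images list of [masked_image]s (full resolution, >= 2).
#' @param start_index index of the starting reference image.
#' @param n_iter number of model iterations (the model typically converges
#'   after one to two).
#' @param rescale_factor integer voxel-size multiplier applied before
#'   registration (transforms remain valid at full resolution).
#' @param grid_spacing requested B-spline control spacing, mm.
#' @param pad_mm padding added around the reference domain so neighbouring
#'   specimens stay inside it; defaults to 10% of the largest extent.
#' @param opts [registration_options()] for both registration stages.
#' @param verbose print per-iteration diagnostics.
#' @return An object of class `sdm_state`: list with `reference` (the
#'   canonical [masked_image] at registration resolution), `transforms`
#'   (per-specimen composite transforms from the final iteration, canonical
#'   to individual), `diagnostics` (data.frame: iteration, dice, msd,
#'   hausdorff vs the previous reference), and `params`.
#' @export
build_canonical <- function(images, start_index = 1, n_iter = 2,
                            rescale_factor = 10, grid_spacing = 20,
                            pad_mm = NULL, opts = registration_options(),
                            verbose = FALSE) {
  if (length(images) < 2) stop("need at least two images")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (start_index < 1 || start_index > length(images)) stop("invalid start_index")
  low <- lapply(images, rescale_by_factor, factor = rescale_factor)

  ref0 <- low[[start_index]]
  pad_mm <- pad_mm %||% (0.1 * max(dim(ref0$values) * ref0$spacing))
  pad_vox <- ceiling(pad_mm / ref0$spacing)
  geom <- list(dim = dim(ref0$values) + 2L * as.integer(pad_vox),
               spacing = ref0$spacing,
               origin = ref0$origin - pad_vox * ref0$spacing)
  reference <- apply_transform(ref0, NULL, geom)

  diagnostics <- data.frame()
  transforms <- NULL
  for (it in seq_len(n_iter)) {
    prev <- reference
    sims <- lapply(low, function(img) register_similarity(prev, img, opts))
    sim_avg <- average_similarity(sims)
    aligned <- apply_transform(prev, invert_transform(sim_avg), geom)

    sims2 <- lapply(low, function(img) register_similarity(aligned, img, opts))
    bsps <- lapply(seq_along(low), function(i) {
      register_bspline(aligned, low[[i]], grid_spacing, sims2[[i]], opts)
    })
    transforms <- lapply(seq_along(low), function(i) {
      compose_transforms(bsps[[i]], sims2[[i]])
    })
    warped <- lapply(seq_along(low), function(i) {
      apply_transform(low[[i]], transforms[[i]], geom)
    })
    avg_img <- average_images(warped, geom)
    bsp_avg <- average_bspline(bsps)
    bsp_inv <- invert_bspline_approx(bsp_avg, tol = 0.5 * min(geom$spacing))
    reference <- apply_transform(avg_img, bsp_inv, geom)

    sd <- surface_distances(prev, reference)
    dc <- dice(prev, reference)
    diagnostics <- rbind(diagnostics, data.frame(
      iteration = it, dice = dc, msd = sd$msd, hausdorff = sd$hausdorff,
      mean_scale = mean(vapply(sims2, `[[`, numeric(1), "scale")),
      inversion_residual = attr(bsp_inv, "residual")))
    if (verbose) {
      message(sprintf("SDM iteration %d: Dice %.4f, MSD %.4f mm, Hausdorff %.3f mm",
                      it, dc, sd$msd, sd$hausdorff))
    }
  }
  structure(list(reference = reference, transforms = transforms,
                 similarity = sims2, bsplines = bsps,
                 diagnostics = diagnostics,
                 params = list(start_index = start_index, n_iter = n_iter,
                               rescale_factor = rescale_factor,
                               grid_spacing = grid_spacing, pad_mm = pad_mm)),
            class = "sdm_state")
}

#' @export
print.sdm_state <- function(x, ...) {
  cat("sdm_state: canonical bone after", x$params$n_iter, "iteration(s)\n")
  cat("  reference:", paste(dim(x$reference$values), collapse = " x "),
      "voxels at", signif(x$reference$spacing[1], 4), "mm\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}
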