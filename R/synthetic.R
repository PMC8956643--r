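# Synthetic bone populations with known ground truth. Real micro-CT
# populations are large and rarely redistributable, so every pipeline stage
# is validated against stylized bones: a smooth closed outer surface with a
# cortical shell and a porous interior whose local fill fraction follows a
# prescribed smooth BV/TV field. Inter-individual variation is generated
# from known similarity transforms plus smooth random warps, and group
# effects are planted in a stored region — so registration, masking, BV/TV
# mapping and statistics can all be checked against the generating truth.

#' Parameters of a synthetic bone
#'
#' @param semi_axes ellipsoid semi-axes (mm) of the outer surface.
#' @param surface_amp amplitude of the smooth random perturbation of the
#'   outer surface (dimensionless, relative to the implicit ellipsoid
#'   function; 0 gives an exact ellipsoid).
#' @param shell_mm cortical shell thickness, mm.
#' @param texture_sigma_mm correlation length of the trabecular texture
#'   noise, mm.
#' @export
bone_shape_params <- function(semi_axes = c(7, 9, 13), surface_amp = 0.08,
                              shell_mm = 1.5, texture_sigma_mm = 0.25) {
  list(semi_axes = semi_axes, surface_amp = surface_amp, shell_mm = shell_mm,
       texture_sigma_mm = texture_sigma_mm)
}

#' Parameters of the prescribed BV/TV field
#'
#' The interior fill fraction is `base + slope . (x - centre)/extent`, plus
#' a Gaussian bump of amplitude `bump_amp` at `bump_center` (relative
#' coordinates in \[-0.5, 0.5\]) with width `bump_sigma` (relative), clamped
#' to \[0.05, 0.6\].
#' @export
bvtv_field_params <- function(base = 0.3, slope = c(0, 0, 0.15),
                              bump_center = NULL, bump_amp = 0,
                              bump_sigma = 0.2) {
  list(base = base, slope = slope, bump_center = bump_center,
       bump_amp = bump_amp, bump_sigma = bump_sigma)
}

# Smooth unit-variance Gaussian random field on a voxel grid (white noise
# convolved with a Gaussian kernel of width sigma_mm).
smooth_noise_field <- function(dims, spacing, sigma_mm) {
  noise <- array(stats::rnorm(prod(dims)), dims)
  r <- pmax(1L, ceiling(3 * sigma_mm / spacing))
  kax <- lapply(1:3, function(a) {
    x <- (-r[a]:r[a]) * spacing[a]
    w <- exp(-x^2 / (2 * sigma_mm^2)); w / sum(w)
  })
  k <- outer(outer(kax[[1]], kax[[2]]), kax[[3]])
  dim(k) <- 2L * r + 1L
  sm <- conv3_fft(noise, k)
  (sm - mean(sm)) / stats::sd(sm)
}

# Evaluate the prescribed BV/TV field at world points (template frame).
bvtv_field_at <- function(pts, fp, domain_center, domain_extent) {
  rel <- sweep(sweep(pts, 2, domain_center, "-"), 2, domain_extent, "/")
  p <- fp$base + as.numeric(rel %*% fp$slope)
  if (!is.null(fp$bump_center) && fp$bump_amp != 0) {
    d2 <- rowSums(sweep(rel, 2, fp$bump_center, "-")^2)
    p <- p + fp$bump_amp * exp(-d2 / (2 * fp$bump_sigma^2))
  }
  pmin(pmax(p, 0), 0.95)
}

#' Generate one synthetic bone image
#'
#' Builds a binary bone volume on an isotropic grid: a smooth closed outer
#' surface (randomized ellipsoid), a cortical shell of the configured
#' thickness, and an interior filled with thresholded smoothed noise whose
#' local fill fraction tracks the prescribed field `p(x)` (the noise is
#' rank-transformed to uniform, so the realized fill matches `p` closely on
#' homogenisation-scale windows).
#'
#' @param shape a [bone_shape_params()] list.
#' @param field a [bvtv_field_params()] list.
#' @param voxel_size isotropic voxel size, mm.
#' @param margin_mm empty margin around the bone, mm.
#' @param seed RNG seed; the same seed reproduces the volume bit-identically.
#' @return list with `image` (a [masked_image]; mask = filled periosteal
#'   volume) and `truth` (shell/interior masks and the generating
#'   parameters).
#' @export
make_bone <- function(shape = bone_shape_params(), field = bvtv_field_params(),
                      voxel_size = 0.5, margin_mm = 4, seed = 1) {
  half <- shape$semi_axes + margin_mm
  dims <- as.integer(ceiling(2 * half / voxel_size))
  if (any(dims > 256L)) stop("image dimensions exceed 256^3; increase voxel_size")
  origin <- -half + voxel_size / 2
  spacing <- rep(voxel_size, 3)
  if (any(shape$shell_mm >= shape$semi_axes)) stop("shell thicker than the object")
  with_seed(seed, {
    ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * voxel_size)
    q <- array(rep(ax[[1]]^2 / shape$semi_axes[1]^2, times = dims[2] * dims[3]), dims) +
      array(rep(rep(ax[[2]]^2 / shape$semi_axes[2]^2, each = dims[1]), times = dims[3]), dims) +
      array(rep(ax[[3]]^2 / shape$semi_axes[3]^2, each = dims[1] * dims[2]), dims)
    if (shape$surface_amp > 0) {
      psi <- smooth_noise_field(dims, spacing, sigma_mm = max(shape$semi_axes) / 2)
      q <- q + shape$surface_amp * psi
    }
    inside <- q <= 1
    interior <- erode_binary(inside, shape$shell_mm, spacing)
    shell <- inside & !interior
    eta <- smooth_noise_field(dims, spacing, shape$texture_sigma_mm)
    u <- array(rank(eta, ties.method = "first") / length(eta), dims)
    pts <- grid_coords(list(dim = dims, spacing = spacing, origin = origin))
    p <- array(bvtv_field_at(pts, field, c(0, 0, 0), 2 * half), dims)
    trab <- interior & (u <= p)
    values <- array(as.numeric(shell | trab), dims)
    img <- masked_image(values, array(as.integer(inside), dims),
                        spacing = spacing, origin = origin)
    truth <- list(shell = shell, interior = interior, field = field,
                  shape = shape, seed = seed, p = p)
    list(image = img, truth = truth)
  })
}

random_similarity <- function(center, scale_range, max_rot_deg, max_trans_mm) {
  s <- stats::runif(1, scale_range[1], scale_range[2])
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, -max_rot_deg, max_rot_deg) * pi / 180
  tr <- stats::runif(3, -max_trans_mm, max_trans_mm)
  similarity_transform(rotation = rotvec_to_quat(axis * ang), scale = s,
                       translation = tr, center = center)
}

random_warp <- function(domain_lo, domain_hi, grid_mm, amp_mm) {
  extent <- domain_hi - domain_lo
  n <- pmax(1L, as.integer(round_half_up(extent / grid_mm)))
  g <- extent / n
  m <- n + 3L
  disp <- array(stats::rnorm(prod(m) * 3, sd = amp_mm), c(m, 3))
  bspline_transform(domain_lo - g, g, m, disp)
}

#' Generate a synthetic bone population with known ground truth
#'
#' One global template defines the homology; each specimen is the template
#' pulled through a random similarity transform (scale 0.9-1.1, rotation up
#' to 15 degrees, translation up to `max_trans_mm`) composed with a smooth
#' random B-spline warp, then textured independently in its own space.
#' Specimens in the second group have their BV/TV field raised by
#' `effect_size` times the baseline inside a stored spherical region of the
#' template frame.
#'
#' @param n_per_group specimens per group (>= 2).
#' @param groups group labels (length 2, or 1 for a single group).
#' @param effect_size relative BV/TV increase planted in group 2 (0 gives
#'   exchangeable groups, the FWER null construction).
#' @param warp_scale_mm sd of the random control-point displacements, mm
#'   (0 disables warping).
#' @param warp_grid_mm control spacing of the random warp, mm.
#' @param max_trans_mm translation range of the random similarity, mm.
#' @param effect_center,effect_radius centre (template frame, mm) and
#'   radius (mm) of the planted-effect region.
#' @param shape,field,voxel_size,seed as in [make_bone()].
#' @return list with `images` (list of [masked_image]), `groups` (labels per
#'   specimen) and `truth` (template, per-specimen generating transforms
#'   mapping specimen space to template space, effect region, seeds).
#' @export
make_population <- function(n_per_group = 3, groups = c("A", "B"),
                            effect_size = 0, warp_scale_mm = 1,
                            warp_grid_mm = 12, max_trans_mm = 2,
                            effect_center = c(0, 0, 6), effect_radius = 5,
                            shape = bone_shape_params(),
                            field = bvtv_field_params(),
                            voxel_size = 0.5, seed = 42) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  template <- make_bone(shape, field, voxel_size, seed = seed)
  geom <- image_geometry(template$image)
  dom_lo <- geom$origin - geom$spacing / 2
  dom_hi <- dom_lo + geom$dim * geom$spacing
  center <- (dom_lo + dom_hi) / 2
  labels <- rep(groups, each = n_per_group)[seq_len(n_per_group * length(groups))]
  n <- length(labels)
  tmpl_interior <- template$truth$interior
  specimens <- vector("list", n)
  gts <- vector("list", n)
  for (i in seq_len(n)) {
    spec_seed <- seed + 1000L * i
    with_seed(spec_seed, {
      sim <- random_similarity(center, c(0.9, 1.1), 15, max_trans_mm)
      warp <- if (warp_scale_mm > 0) {
        random_warp(dom_lo, dom_hi, warp_grid_mm, warp_scale_mm)
      } else NULL
      # generating map G_i: specimen space -> template space
      G <- if (is.null(warp)) sim else compose_transforms(sim, warp)
      pts <- grid_coords(geom)
      tp <- transform_points(G, pts)
      tidx <- world_to_index(geom, tp)
      inside <- array(interp_nearest(array(as.numeric(template$truth$interior |
                                                        template$truth$shell),
                                           geom$dim), tidx) > 0.5, geom$dim)
      interior <- array(interp_nearest(array(as.numeric(tmpl_interior), geom$dim),
                                       tidx) > 0.5, geom$dim)
      shell <- inside & !interior
      p <- bvtv_field_at(tp, field, c(0, 0, 0),
                         2 * (shape$semi_axes + 4))
      if (labels[i] == groups[length(groups)] && effect_size != 0 && length(groups) > 1) {
        in_region <- rowSums(sweep(tp, 2, effect_center, "-")^2) <= effect_radius^2
        p <- p * (1 + effect_size * in_region)
      }
      p <- array(pmin(pmax(p, 0), 0.95), geom$dim)
      eta <- smooth_noise_field(geom$dim, geom$spacing, shape$texture_sigma_mm)
      u <- array(rank(eta, ties.method = "first") / length(eta), geom$dim)
      trab <- interior & (u <= p)
      img <- masked_image(array(as.numeric(shell | trab), geom$dim),
                          array(as.integer(inside), geom$dim),
                          spacing = geom$spacing, origin = geom$origin)
      specimens[[i]] <- img
      gts[[i]] <- list(similarity = sim, warp = warp, seed = spec_seed,
                       group = labels[i])
    })
  }
  structure(list(images = specimens, groups = labels,
                 truth = list(template = template, specimens = gts,
                              effect_center = effect_center,
                              effect_radius = effect_radius,
                              effect_size = effect_size, seed = seed)),
            class = "synthetic_population")
}
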