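# Parametric spatial transforms. All transforms are point maps in world
# coordinates (mm) in the resampling convention: they map fixed/canonical
# space points into moving/individual space. Resampling an image through a
# transform therefore pulls moving-image values onto the fixed grid, and the
# same map pushes canonical mesh vertices onto an individual bone.

## ---- quaternion helpers ----

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("zero quaternion")
  q / n
}

quat_conj <- function(q) c(q[1], -q[2:4])

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + c(
      a[3] * b[4] - a[4] * b[3],
      a[4] * b[2] - a[2] * b[4],
      a[2] * b[3] - a[3] * b[2]))
}

quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

matrix_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s, (R[2, 3] + R[3, 2]) / s, s / 4)
    }
  }
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  q
}

rotvec_to_quat <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(c(1, v / 2))
  quat_normalize(c(cos(th / 2), sin(th / 2) * v / th))
}

quat_to_rotvec <- function(q) {
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  th <- 2 * acos(pmin(1, q[1]))
  s <- sqrt(max(0, 1 - q[1]^2))
  if (s < 1e-12) return(q[2:4] * 2)
  th * q[2:4] / s
}

rotation_angle_deg <- function(q) {
  q <- quat_normalize(q)
  2 * acos(pmin(1, abs(q[1]))) * 180 / pi
}

## ---- similarity transform ----

#' Similarity transform (rotation, isotropic scale, translation)
#'
#' Maps a point `x` to `s * R * (x - center) + center + translation`; the
#' centre of rotation is fixed, which keeps the population of transforms
#' averageable component-wise.
#'
#' @param rotation unit quaternion (w, x, y, z).
#' @param scale positive isotropic scale factor.
#' @param translation length-3 vector, mm.
#' @param center fixed rotation centre, mm.
#' @export
similarity_transform <- function(rotation = c(1, 0, 0, 0), scale = 1,
                                 translation = c(0, 0, 0), center = c(0, 0, 0)) {
  if (scale <= 0) stop("scale must be > 0")
  structure(list(rotation = quat_normalize(rotation), scale = as.numeric(scale),
                 translation = rep_len(as.numeric(translation), 3),
                 center = rep_len(as.numeric(center), 3)),
            class = c("similarity_transform", "chma_transform"))
}

#' @rdname similarity_transform
#' @export
identity_transform <- function(center = c(0, 0, 0)) similarity_transform(center = center)

#' Map points through a transform
#'
#' Applies the world-coordinate point map of a transform (fixed-to-moving
#' direction) to an `N x 3` matrix of points.
#'
#' @param t a transform object.
#' @param pts N x 3 matrix of world coordinates, mm.
#' @return N x 3 matrix of mapped points.
#' @export
transform_points <- function(t, pts) UseMethod("transform_points")

#' @export
transform_points.similarity_transform <- function(t, pts) {
  R <- quat_to_matrix(t$rotation)
  centred <- sweep(pts, 2, t$center, "-")
  mapped <- t$scale * (centred %*% t(R))
  sweep(mapped, 2, t$center + t$translation, "+")
}

#' Invert a transform
#'
#' Similarity transforms invert in closed form. For B-spline transforms see
#' [invert_bspline_approx()].
#' @param t a transform.
#' @export
invert_transform <- function(t) UseMethod("invert_transform")

#' @export
invert_transform.similarity_transform <- function(t) {
  Rt <- t(quat_to_matrix(t$rotation))
  similarity_transform(rotation = quat_conj(t$rotation), scale = 1 / t$scale,
                       translation = as.numeric(-(Rt %*% t$translation) / t$scale),
                       center = t$center)
}

## ---- cubic B-spline free-form deformation ----

cubic_bspline_weights <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

#' Cubic B-spline free-form deformation
#'
#' A displacement field parameterized by a regular control-point grid:
#' control point `(i,j,k)` (0-based) sits at `grid_origin + (i,j,k) *
#' grid_spacing` and carries a 3-vector displacement (mm). The field is the
#' tensor-product cubic B-spline of the control displacements and is C2
#' inside its support; the transform maps `x` to `x + u(x)`.
#'
#' @param grid_origin position of control point (0,0,0), mm.
#' @param grid_spacing per-axis control spacing, mm.
#' @param grid_dims per-axis control-point (coefficient) counts.
#' @param displacements array `grid_dims x 3` of control displacements, mm
#'   (zero if omitted).
#' @export
bspline_transform <- function(grid_origin, grid_spacing, grid_dims, displacements = NULL) {
  grid_dims <- as.integer(rep_len(grid_dims, 3))
  if (any(grid_dims < 4L)) stop("degenerate control grid: need >= 4 coefficients (1 interval) per axis")
  if (is.null(displacements)) displacements <- array(0, c(grid_dims, 3))
  stopifnot(identical(dim(displacements), c(grid_dims, 3L)))
  structure(list(grid_origin = rep_len(as.numeric(grid_origin), 3),
                 grid_spacing = rep_len(as.numeric(grid_spacing), 3),
                 grid_dims = grid_dims,
                 displacements = displacements),
            class = c("bspline_transform", "chma_transform"))
}

# Displacements (N x 3) of a B-spline FFD at arbitrary points. Outside the
# valid support (where fewer than 4 basis functions overlap) the field is
# extended as a constant along each axis — mesh vertices just past the
# image edge stay usable and the field remains bounded everywhere, which
# the fixed-point inversion relies on.
bspline_displacement <- function(t, pts) {
  s <- sweep(sweep(pts, 2, t$grid_origin, "-"), 2, t$grid_spacing, "/")
  m <- t$grid_dims
  n <- nrow(pts)
  j0 <- u <- list()
  for (a in 1:3) {
    sa <- pmin(pmax(s[, a], 1), m[a] - 2)
    fl <- floor(sa)
    j <- pmin(pmax(fl - 1, 0), m[a] - 4)
    j0[[a]] <- j
    u[[a]] <- sa - (j + 1)
  }
  w <- lapply(1:3, function(a) cubic_bspline_weights(u[[a]]))
  disp <- matrix(0, n, 3)
  cdisp <- t$displacements
  s1 <- m[1]; s2 <- m[1] * m[2]; s3 <- prod(m)
  for (dz in 0:3) {
    wz <- w[[3]][, dz + 1]
    kz <- (j0[[3]] + dz) * s2
    for (dy in 0:3) {
      wyz <- w[[2]][, dy + 1] * wz
      kyz <- kz + (j0[[2]] + dy) * s1
      for (dx in 0:3) {
        wt <- w[[1]][, dx + 1] * wyz
        idx <- 1 + j0[[1]] + dx + kyz
        disp[, 1] <- disp[, 1] + wt * cdisp[idx]
        disp[, 2] <- disp[, 2] + wt * cdisp[idx + s3]
        disp[, 3] <- disp[, 3] + wt * cdisp[idx + 2 * s3]
      }
    }
  }
  disp
}

#' @export
transform_points.bspline_transform <- function(t, pts) {
  pts + bspline_displacement(t, pts)
}

# Per-axis basis matrix (coordinate values x coefficients) used for fast
# tensor-product evaluation of an FFD over a regular grid of coordinates.
bspline_axis_basis <- function(coords, origin, spacing, m) {
  s <- (coords - origin) / spacing
  fl <- floor(s)
  j0 <- pmin(pmax(fl - 1, 0), m - 4)
  u <- s - (j0 + 1)
  w <- cubic_bspline_weights(u)
  B <- matrix(0, length(coords), m)
  for (k in 0:3) B[cbind(seq_along(coords), j0 + 1 + k)] <- B[cbind(seq_along(coords), j0 + 1 + k)] + w[, k + 1]
  B
}

# Evaluate one displacement component over a regular grid via mode products.
bspline_field_component <- function(coef3d, Bx, By, Bz) {
  ttm3(ttm3(ttm3(coef3d, Bx, 1L), By, 2L), Bz, 3L)
}

## ---- composition ----

#' Compose transforms
#'
#' `compose(a, b)` returns the composite whose point map is `b(a(x))`:
#' transforms are applied in the order listed. In the canonical-bone
#' pipeline the per-specimen transform is `compose(bspline, similarity)` —
#' the free-form deformation acts in the canonical domain (where its control
#' grid is shared by every specimen) and the similarity then carries the
#' point into the individual bone space.
#'
#' @param a,b transforms (either may itself be composite).
#' @export
compose_transforms <- function(a, b) {
  parts <- c(transform_list(a), transform_list(b))
  structure(list(transforms = parts), class = c("composite_transform", "chma_transform"))
}

transform_list <- function(t) {
  if (inherits(t, "composite_transform")) t$transforms else list(t)
}

#' @export
transform_points.composite_transform <- function(t, pts) {
  for (part in t$transforms) pts <- transform_points(part, pts)
  pts
}

#' @export
print.chma_transform <- function(x, ...) {
  if (inherits(x, "similarity_transform")) {
    cat("similarity_transform: scale", signif(x$scale, 6),
        "| rotation", signif(rotation_angle_deg(x$rotation), 4), "deg",
        "| translation", paste(signif(x$translation, 4), collapse = ", "), "mm\n")
  } else if (inherits(x, "bspline_transform")) {
    cat("bspline_transform: grid", paste(x$grid_dims, collapse = " x "),
        "coefficients, spacing", paste(signif(x$grid_spacing, 4), collapse = ", "), "mm,",
        "max |displacement|", signif(max(abs(x$displacements)), 4), "mm\n")
  } else {
    cat("composite_transform of", length(x$transforms), "parts (applied in order):\n")
    for (p in x$transforms) print(p)
  }
  invisible(x)
}

## ---- serialization ----

#' Read and write transforms
#'
#' Transforms are serialized to an ITK-style transform text file (parameter
#' lists per transform) together with a JSON sidecar carrying the full
#' structured representation (quaternion, scale, centre; control-grid
#' origin/spacing/dims and displacements). The JSON sidecar is authoritative
#' on read.
#'
#' @param t a transform.
#' @param path output path (`.tfm`); `<path>.json` is written alongside.
#' @export
write_transform <- function(t, path) {
  lines <- c("#Insight Transform File V1.0")
  idx <- 0
  for (part in transform_list(t)) {
    lines <- c(lines, paste0("#Transform ", idx))
    if (inherits(part, "similarity_transform")) {
      vq <- part$rotation[c(2, 3, 4, 1)] # ITK versor order (x, y, z, w)
      lines <- c(lines,
        "Transform: Similarity3DTransform_double_3_3",
        paste("Parameters:", paste(formatC(c(vq[1:3], part$translation, part$scale),
                                           format = "g", digits = 17), collapse = " ")),
        paste("FixedParameters:", paste(formatC(part$center, format = "g", digits = 17),
                                        collapse = " ")))
    } else if (inherits(part, "bspline_transform")) {
      lines <- c(lines,
        "Transform: BSplineTransform_double_3_3",
        paste("Parameters:", paste(formatC(as.numeric(part$displacements),
                                           format = "g", digits = 17), collapse = " ")),
        paste("FixedParameters:", paste(formatC(c(part$grid_dims, part$grid_origin,
                                                  part$grid_spacing, as.numeric(diag(3))),
                                                format = "g", digits = 17), collapse = " ")))
    } else stop("cannot serialize transform of class ", paste(class(part), collapse = "/"))
    idx <- idx + 1
  }
  writeLines(lines, path)
  jsonlite::write_json(transform_to_list(t), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

transform_to_list <- function(t) {
  if (inherits(t, "composite_transform")) {
    list(type = "composite", transforms = lapply(t$transforms, transform_to_list))
  } else if (inherits(t, "similarity_transform")) {
    list(type = "similarity", rotation = t$rotation, scale = t$scale,
         translation = t$translation, center = t$center)
  } else {
    list(type = "bspline", grid_origin = t$grid_origin, grid_spacing = t$grid_spacing,
         grid_dims = t$grid_dims, displacements = as.numeric(t$displacements))
  }
}

transform_from_list <- function(x) {
  switch(x$type,
    composite = {
      parts <- lapply(x$transforms, transform_from_list)
      structure(list(transforms = parts), class = c("composite_transform", "chma_transform"))
    },
    similarity = similarity_transform(unlist(x$rotation), x$scale,
                                      unlist(x$translation), unlist(x$center)),
    bspline = bspline_transform(unlist(x$grid_origin), unlist(x$grid_spacing),
                                unlist(x$grid_dims),
                                array(unlist(x$displacements), c(unlist(x$grid_dims), 3))),
    stop("unknown transform type ", x$type))
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  json <- if (file.exists(paste0(path, ".json"))) paste0(path, ".json") else path
  transform_from_list(jsonlite::read_json(json, simplifyVector = FALSE))
}
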