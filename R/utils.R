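#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# round-half-up, used for B-spline interval counts
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trilinear interpolation of a 3D array at continuous 0-based voxel indices.
# pts: N x 3 matrix. Points outside the array domain return `fill`.
interp_trilinear <- function(arr, pts, fill = 0) {
  d <- dim(arr)
  stopifnot(length(d) == 3L, ncol(pts) == 3L)
  n <- nrow(pts)
  out <- rep(fill, n)
  if (n == 0L) return(out)
  inside <- pts[, 1] >= 0 & pts[, 1] <= d[1] - 1 &
    pts[, 2] >= 0 & pts[, 2] <= d[2] - 1 &
    pts[, 3] >= 0 & pts[, 3] <= d[3] - 1
  inside[is.na(inside)] <- FALSE
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  i0 <- pmin(pmax(floor(p[, 1]), 0), max(d[1] - 2, 0))
  j0 <- pmin(pmax(floor(p[, 2]), 0), max(d[2] - 2, 0))
  k0 <- pmin(pmax(floor(p[, 3]), 0), max(d[3] - 2, 0))
  fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
  s1 <- d[1]; s2 <- d[1] * d[2]
  base <- 1 + i0 + j0 * s1 + k0 * s2
  v <- numeric(nrow(p))
  for (dz in 0:1) {
    wz <- if (dz == 0) 1 - fz else fz
    for (dy in 0:1) {
      wy <- if (dy == 0) 1 - fy else fy
      for (dx in 0:1) {
        wx <- if (dx == 0) 1 - fx else fx
        idx <- base + dx + dy * s1 + dz * s2
        v <- v + wx * wy * wz * arr[idx]
      }
    }
  }
  out[inside] <- v
  out
}

# Nearest-neighbour lookup at continuous 0-based voxel indices.
interp_nearest <- function(arr, pts, fill = 0) {
  d <- dim(arr)
  n <- nrow(pts)
  out <- rep(fill, n)
  if (n == 0L) return(out)
  i <- round_half_up(pts[, 1]); j <- round_half_up(pts[, 2]); k <- round_half_up(pts[, 3])
  inside <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 & k >= 0 & k <= d[3] - 1
  inside[is.na(inside)] <- FALSE
  idx <- 1 + i[inside] + j[inside] * d[1] + k[inside] * d[1] * d[2]
  out[inside] <- arr[idx]
  out
}

# Mode-n product of a 3D array with a matrix (rows index the new dimension).
ttm3 <- function(a, m, mode) {
  d <- dim(a)
  if (mode == 1L) {
    array(m %*% matrix(a, d[1], d[2] * d[3]), c(nrow(m), d[2], d[3]))
  } else if (mode == 2L) {
    ap <- aperm(a, c(2L, 1L, 3L))
    r <- array(m %*% matrix(ap, d[2], d[1] * d[3]), c(nrow(m), d[1], d[3]))
    aperm(r, c(2L, 1L, 3L))
  } else {
    ap <- aperm(a, c(3L, 1L, 2L))
    r <- array(m %*% matrix(ap, d[3], d[1] * d[2]), c(nrow(m), d[1], d[2]))
    aperm(r, c(2L, 3L, 1L))
  }
}

# Central-difference gradient of a 3D array, in physical units (per mm).
array_gradient <- function(arr, spacing) {
  d <- dim(arr)
  g <- vector("list", 3L)
  for (ax in 1:3) {
    hi <- lo <- arr
    n <- d[ax]
    idx_hi <- c(2:n, n)
    idx_lo <- c(1, 1:(n - 1))
    if (ax == 1) { hi <- arr[idx_hi, , , drop = FALSE]; lo <- arr[idx_lo, , , drop = FALSE] }
    if (ax == 2) { hi <- arr[, idx_hi, , drop = FALSE]; lo <- arr[, idx_lo, , drop = FALSE] }
    if (ax == 3) { hi <- arr[, , idx_hi, drop = FALSE]; lo <- arr[, , idx_lo, drop = FALSE] }
    step <- rep(2, n); step[1] <- 1; step[n] <- 1
    garr <- (hi - lo)
    if (ax == 1) garr <- sweep(garr, 1, step * spacing[ax], "/")
    if (ax == 2) garr <- sweep(garr, 2, step * spacing[ax], "/")
    if (ax == 3) garr <- sweep(garr, 3, step * spacing[ax], "/")
    dim(garr) <- d
    g[[ax]] <- garr
  }
  g
}
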