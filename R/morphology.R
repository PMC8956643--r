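# 3D binary morphology with spherical (physically sized) structuring
# elements. Dilation/erosion are computed as FFT convolutions with a ball
# kernel — exact for binary inputs after thresholding the voxel counts — so
# radii are specified in mm and respect anisotropic spacing.

ball_kernel <- function(radius_mm, spacing) {
  r_vox <- pmax(0L, floor(radius_mm / spacing + 1e-9))
  dims <- 2L * r_vox + 1L
  ax <- lapply(1:3, function(a) ((-r_vox[a]):(r_vox[a])) * spacing[a])
  dx2 <- array(rep(ax[[1]]^2, times = dims[2] * dims[3]), dims)
  dy2 <- array(rep(rep(ax[[2]]^2, each = dims[1]), times = dims[3]), dims)
  dz2 <- array(rep(ax[[3]]^2, each = dims[1] * dims[2]), dims)
  array(as.numeric(dx2 + dy2 + dz2 <= radius_mm^2 + 1e-9), dims)
}

# Linear convolution of a 3D array with a (small, odd-sized) kernel,
# "same" output size, zero padding outside.
conv3_fft <- function(a, k) {
  da <- dim(a); dk <- dim(k)
  dp <- da + dk - 1L
  pa <- array(0, dp); pa[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- a
  pk <- array(0, dp); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  conv <- Re(fft(fft(pa) * fft(pk), inverse = TRUE)) / prod(dp)
  r <- (dk - 1L) / 2L
  conv[r[1] + seq_len(da[1]), r[2] + seq_len(da[2]), r[3] + seq_len(da[3]), drop = FALSE]
}

dilate_binary <- function(x, radius_mm, spacing) {
  if (radius_mm <= 0) return(x != 0)
  k <- ball_kernel(radius_mm, spacing)
  conv3_fft(array(as.numeric(x != 0), dim(x)), k) > 0.5
}

erode_binary <- function(x, radius_mm, spacing) {
  if (radius_mm <= 0) return(x != 0)
  k <- ball_kernel(radius_mm, spacing)
  conv3_fft(array(as.numeric(x != 0), dim(x)), k) > sum(k) - 0.5
}

# Closing pads the domain first so that dilation is not clipped at the
# image border.
close_binary <- function(x, radius_mm, spacing) {
  if (radius_mm <= 0) return(x != 0)
  r_vox <- pmax(1L, ceiling(radius_mm / spacing))
  d <- dim(x)
  dp <- d + 2L * r_vox
  pad <- array(FALSE, dp)
  pad[r_vox[1] + seq_len(d[1]), r_vox[2] + seq_len(d[2]), r_vox[3] + seq_len(d[3])] <- x != 0
  cl <- erode_binary(dilate_binary(pad, radius_mm, spacing), radius_mm, spacing)
  cl[r_vox[1] + seq_len(d[1]), r_vox[2] + seq_len(d[2]), r_vox[3] + seq_len(d[3]), drop = FALSE]
}

# Shift a 3D logical array by one voxel along an axis, filling with FALSE.
shift1 <- function(x, axis, dir) {
  d <- dim(x)
  out <- array(FALSE, d)
  n <- d[axis]
  if (n < 2L) return(out)
  src <- if (dir > 0) 1:(n - 1) else 2:n
  dst <- if (dir > 0) 2:n else 1:(n - 1)
  if (axis == 1) out[dst, , ] <- x[src, , ]
  else if (axis == 2) out[, dst, ] <- x[, src, ]
  else out[, , dst] <- x[, , src]
  out
}

neighbours6 <- function(x) {
  acc <- array(FALSE, dim(x))
  for (a in 1:3) for (s in c(-1, 1)) acc <- acc | shift1(x, a, s)
  acc
}

# Fill internal cavities: background regions (6-connectivity) not reachable
# from the image border become foreground.
fill_holes <- function(x) {
  x <- x != 0
  d <- dim(x)
  bg <- !x
  reach <- array(FALSE, d)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE; border[, c(1, d[2]), ] <- TRUE; border[, , c(1, d[3])] <- TRUE
  frontier <- border & bg
  reach <- frontier
  while (any(frontier)) {
    frontier <- neighbours6(frontier) & bg & !reach
    reach <- reach | frontier
  }
  x | (bg & !reach)
}

# Largest 6-connected foreground component (with a count of components).
largest_component <- function(x) {
  x <- x != 0
  remaining <- x
  best <- NULL; best_size <- -1L; n_comp <- 0L
  while (any(remaining)) {
    n_comp <- n_comp + 1L
    seed <- array(FALSE, dim(x))
    seed[which(remaining)[1]] <- TRUE
    comp <- seed
    frontier <- seed
    while (any(frontier)) {
      frontier <- neighbours6(frontier) & remaining & !comp
      comp <- comp | frontier
    }
    sz <- sum(comp)
    if (sz > best_size) { best <- comp; best_size <- sz }
    remaining <- remaining & !comp
  }
  list(component = best, n_components = n_comp)
}
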