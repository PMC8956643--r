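# Shared fixtures: small geometric phantoms built in code.

# Solid ball of given radius (mm), centred in the volume.
make_ball_image <- function(radius_mm = 5, spacing = 0.5, margin_mm = 2) {
  half <- radius_mm + margin_mm
  n <- ceiling(2 * half / spacing)
  origin <- rep(-half + spacing / 2, 3)
  ax <- origin[1] + (seq_len(n) - 1) * spacing
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  inside <- r2 <= radius_mm^2
  masked_image(array(as.numeric(inside), rep(n, 3)),
               array(as.integer(inside), rep(n, 3)),
               spacing = rep(spacing, 3), origin = origin)
}

# Hollow sphere: shell between r_inner and r_outer (mm).
make_hollow_sphere <- function(r_outer = 8, r_inner = 6.5, spacing = 0.5,
                               margin_mm = 2) {
  half <- r_outer + margin_mm
  n <- ceiling(2 * half / spacing)
  origin <- rep(-half + spacing / 2, 3)
  ax <- origin[1] + (seq_len(n) - 1) * spacing
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  shell <- r2 <= r_outer^2 & r2 > r_inner^2
  list(image = masked_image(array(as.numeric(shell), rep(n, 3)),
                            array(as.integer(r2 <= r_outer^2), rep(n, 3)),
                            spacing = rep(spacing, 3), origin = origin),
       interior = r2 <= r_inner^2, shell = shell)
}

# Axis-aligned solid box given world bounds (mm) inside a fixed grid.
make_box_mask <- function(dims, spacing, origin, lo, hi) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing[a])
  inx <- ax[[1]] >= lo[1] & ax[[1]] <= hi[1]
  iny <- ax[[2]] >= lo[2] & ax[[2]] <= hi[2]
  inz <- ax[[3]] >= lo[3] & ax[[3]] <= hi[3]
  outer(outer(inx, iny, "&"), inz, "&")
}

# Small synthetic bone shared by several tests (cached per session).
small_bone <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_bone(seed = 101)
    }
    cache
  }
})

# Regular tetrahedron with edge a centred at the origin.
regular_tet <- function(a = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(8) * a
  tet_mesh(v, matrix(1:4, 1))
}

right_corner_tet <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), matrix(1:4, 1))
}
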