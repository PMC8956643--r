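test_that("bvtv_sphere equals exhaustive voxel enumeration on random configurations", {
  b <- small_bone()
  img <- b$image
  tm <- array(as.integer(b$truth$interior), dim(img$values))
  gc <- chma:::grid_coords(img)
  set.seed(42)
  for (k in 1:10) {
    ctr <- stats::runif(3, -4, 4)
    r <- stats::runif(1, 1.5, 3.5)
    fast <- bvtv_sphere(img$values, tm, ctr, r, min_voxels = 1,
                        spacing = img$spacing, origin = img$origin)
    sel <- rowSums(sweep(gc, 2, ctr, "-")^2) <= r^2 & as.vector(tm) > 0
    brute <- if (sum(sel) >= 1) sum(img$values[sel] > 0.5) / sum(sel) else NA_real_
    expect_identical(fast, brute)
  }
})

test_that("bvtv_sphere handles homogeneous regions and missing data", {
  d <- c(40, 40, 40); sp <- rep(0.5, 3); or <- rep(0.25, 3)
  solid <- array(1, d)
  expect_equal(bvtv_sphere(solid, solid, c(10, 10, 10), 3,
                           spacing = sp, origin = or), 1.0)
  empty <- array(0, d)
  expect_equal(bvtv_sphere(empty, solid, c(10, 10, 10), 3,
                           spacing = sp, origin = or), 0.0)
  # half-bone half-empty block straddled by the sphere
  half <- array(0, d); half[1:20, , ] <- 1
  v <- bvtv_sphere(half, solid, c(10, 10, 10), 3, spacing = sp, origin = or)
  expect_equal(v, 0.5, tolerance = 0.05)
  # sphere outside the mask -> missing
  expect_true(is.na(bvtv_sphere(solid, empty, c(10, 10, 10), 3,
                                spacing = sp, origin = or)))
})

test_that("background grid has overlapping spheres and covers the mask", {
  b <- small_bone()
  tm <- array(as.integer(b$truth$interior), dim(b$image$values))
  grid <- evaluate_background_grid(b$image, tm, spacing_mm = 2.5)
  expect_equal(grid$sphere_diameter, 5)            # diameter = 2 x spacing
  expect_equal(grid$spacing, rep(2.5, 3))
  # grid bounding box pads the mask bounding box by >= r on every side
  idx <- which(tm > 0, arr.ind = TRUE) - 1
  lo_w <- b$image$origin + apply(idx, 2, min) * b$image$spacing
  hi_w <- b$image$origin + apply(idx, 2, max) * b$image$spacing
  expect_true(all(grid$origin <= lo_w - 2.5 + 1e-9))
  top <- grid$origin + (grid$dims - 1) * grid$spacing
  expect_true(all(top >= hi_w + 2.5 - 1e-9))
})

test_that("a homogeneous random block yields near-constant grid values", {
  set.seed(8)
  d <- c(48, 48, 48); sp <- rep(0.5, 3)
  vals <- array(as.numeric(stats::runif(prod(d)) < 0.30), d)
  img <- masked_image(vals, array(1L, d), sp, c(0.25, 0.25, 0.25))
  grid <- evaluate_background_grid(img, NULL, spacing_mm = 2.5)
  # binomial bound holds for vertices whose sphere lies fully inside the
  # block; edge vertices sample fewer voxels and are noisier by design
  gverts <- chma:::grid_coords(list(dim = grid$dims, spacing = grid$spacing,
                                    origin = grid$origin))
  lo <- img$origin; hi <- img$origin + (d - 1) * sp
  interior <- apply(gverts, 1, function(p) all(p - 2.5 >= lo) && all(p + 2.5 <= hi))
  v <- as.vector(grid$values)[interior]
  expect_false(anyNA(v))
  # binomial bound: a full 2.5 mm sphere at 0.5 mm voxels samples ~515 voxels
  n_vox <- sum(chma:::ball_kernel(2.5, sp))
  se <- sqrt(0.3 * 0.7 / n_vox)
  expect_lt(mean(v) - 0.30, 3 * se / sqrt(length(v)) + 0.005)
  expect_lt(max(abs(v - 0.30)), 4.5 * se)
  expect_gt(mean(abs(v - 0.30) < 2 * se), 0.9)
  v <- as.vector(grid$values)[!is.na(as.vector(grid$values))]
  # halving the sphere (no overlap) must raise the field variance
  grid_half <- evaluate_background_grid(img, NULL, spacing_mm = 2.5)
  v_overlap <- stats::var(v)
  # emulate non-overlapping sampling: spheres of half the radius
  centres <- as.matrix(expand.grid(seq(5, 19, 2.5), seq(5, 19, 2.5), seq(5, 19, 2.5)))
  v_small <- apply(centres, 1, function(ctr) {
    bvtv_sphere(img$values, NULL, ctr, 1.25, spacing = sp, origin = img$origin)
  })
  expect_gt(stats::var(v_small), v_overlap)
})

test_that("trilinear interpolation reproduces linear fields at centroids exactly", {
  grid <- structure(list(origin = c(0, 0, 0), spacing = c(2, 2, 2),
                         dims = c(6L, 6L, 6L),
                         values = array(0, c(6, 6, 6)), sphere_diameter = 4),
                    class = "background_grid")
  gc <- chma:::grid_coords(list(dim = grid$dims, spacing = grid$spacing,
                                origin = grid$origin))
  a <- c(0.03, -0.01, 0.02); b0 <- 0.2
  grid$values <- array(b0 + gc %*% a, grid$dims)
  ball <- make_ball_image(radius_mm = 2.5, spacing = 0.5)
  mesh <- mesh_from_mask(ball$mask, 1.2, spacing = ball$spacing, origin = ball$origin)
  mesh$vertices <- sweep(mesh$vertices, 2, c(5, 5, 5), "+")  # into grid interior
  f <- interpolate_to_centroids(grid, mesh)
  expected <- b0 + element_centroids(mesh) %*% a
  expect_equal(f$value, as.numeric(expected), tolerance = 1e-9)

  # constant grid -> every element that constant
  grid$values <- array(0.37, grid$dims)
  expect_equal(interpolate_to_centroids(grid, mesh)$value,
               rep(0.37, nrow(mesh$elements)))

  # centroid outside the grid is an error
  mesh_out <- mesh
  mesh_out$vertices <- mesh$vertices + 100
  expect_error(interpolate_to_centroids(grid, mesh_out), "outside")
})

test_that("relative BVTV normalizes to mean one and forces the stated arithmetic", {
  f <- structure(data.frame(element_id = 1:2, value = c(0.1, 0.3)),
                 class = c("element_field", "data.frame"))
  r <- relative_bvtv(f)
  expect_equal(r$value, c(0.5, 1.5))
  f2 <- structure(data.frame(element_id = 1:5, value = rep(0.2, 5)),
                  class = c("element_field", "data.frame"))
  expect_equal(relative_bvtv(f2)$value, rep(1, 5))
  set.seed(2)
  f3 <- structure(data.frame(element_id = 1:100, value = stats::runif(100, 0.1, 0.5)),
                  class = c("element_field", "data.frame"))
  expect_equal(mean(relative_bvtv(f3)$value), 1, tolerance = 1e-12)
  f4 <- structure(data.frame(element_id = 1, value = 0),
                  class = c("element_field", "data.frame"))
  expect_error(relative_bvtv(f4), "positive")
})

test_that("the full HMA chain recovers a prescribed smooth BVTV field", {
  fp <- bvtv_field_params(base = 0.3, slope = c(0, 0, 0.7))  # p in ~[0.1, 0.5]
  b <- make_bone(field = fp, seed = 21)
  tm <- array(as.integer(b$truth$interior), dim(b$image$values))
  mesh <- mesh_from_mask(b$truth$interior, 2.5, spacing = b$image$spacing,
                         origin = b$image$origin)
  grid <- evaluate_background_grid(b$image, tm, spacing_mm = 2.5)
  f <- relative_bvtv(interpolate_to_centroids(grid, mesh))
  cents <- element_centroids(mesh)
  p <- chma:::bvtv_field_at(cents, fp, c(0, 0, 0), 2 * (c(8, 9, 13) + 4))
  expect_gte(stats::cor(f$value, p / mean(p)), 0.95)
})
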