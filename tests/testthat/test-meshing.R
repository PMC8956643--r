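test_that("meshing a cube reproduces its volume and edge length", {
  d <- c(30, 30, 30); sp <- rep(0.5, 3); or <- c(0.25, 0.25, 0.25)
  cube <- make_box_mask(d, sp, or, c(2, 2, 2), c(12, 12, 12))  # 10 mm cube
  mesh <- mesh_from_mask(cube, 1, spacing = sp, origin = or)
  vol <- sum(element_volumes(mesh))
  expect_lt(abs(vol - 1000) / 1000, 0.05)
  med <- stats::median(edge_lengths(mesh))
  expect_lt(abs(med - 1) / 1, 0.3)
  expect_true(all(element_volumes(mesh) > 0))
})

test_that("meshing a ball matches the analytic volume and coarser meshes have fewer elements", {
  ball <- make_ball_image(radius_mm = 5, spacing = 0.5)
  mesh1 <- mesh_from_mask(ball$mask, 1, spacing = ball$spacing, origin = ball$origin)
  expect_lt(abs(sum(element_volumes(mesh1)) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125),
            0.05)
  mesh3 <- mesh_from_mask(ball$mask, 3, spacing = ball$spacing, origin = ball$origin)
  expect_lt(nrow(mesh3$elements), nrow(mesh1$elements))
  expect_error(mesh_from_mask(array(0, c(4, 4, 4)), 1), "empty")
})

test_that("disconnected masks are reduced to the largest component with a warning", {
  d <- c(30, 30, 30); sp <- rep(0.5, 3); or <- c(0, 0, 0)
  two <- make_box_mask(d, sp, or, c(1, 1, 1), c(6, 6, 6)) |
    make_box_mask(d, sp, or, c(10, 10, 10), c(12, 12, 12))
  expect_warning(mesh <- mesh_from_mask(two, 1, spacing = sp, origin = or),
                 "largest")
  big <- sum(make_box_mask(d, sp, or, c(1, 1, 1), c(6, 6, 6))) * prod(sp)
  small <- sum(make_box_mask(d, sp, or, c(10, 10, 10), c(12, 12, 12))) * prod(sp)
  vol <- sum(element_volumes(mesh))
  # clearly the big component (coarse cells quantize the volume somewhat)
  expect_lt(abs(vol - big) / big, 0.25)
  expect_gt(vol, 3 * small)
})

test_that("tet-collapse and volume-skew hit their defining endpoints", {
  for (a in c(0.5, 1, 3)) {
    expect_equal(tet_collapse(regular_tet(a)), 1, tolerance = 1e-12)
    expect_equal(volume_skew(regular_tet(a)), 0, tolerance = 1e-9)
  }
  flat <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                   matrix(1:4, 1))
  expect_equal(tet_collapse(flat), 0)
  expect_equal(volume_skew(flat), 1)
})

test_that("quality metrics of the right-corner tetrahedron match geometric oracles", {
  tet <- right_corner_tet()
  # oracle computed from first principles:
  # faces: 3 right triangles (A = 1/2) and the hypotenuse face (A = sqrt(3)/2);
  # V = 1/6; h_i = 3V / A_i; value = min h_i / sqrt(A_i) / (2*sqrt(2)*3^(-3/4))
  V <- 1 / 6
  A <- c(sqrt(3) / 2, 1 / 2, 1 / 2, 1 / 2)
  collapse_oracle <- min(3 * V / A / sqrt(A)) / (2 * sqrt(2) * 3^(-3 / 4))
  expect_equal(tet_collapse(tet), collapse_oracle, tolerance = 1e-12)
  # circumcentre of (0,0,0),(1,0,0),(0,1,0),(0,0,1) is (1/2,1/2,1/2), R = sqrt(3)/2
  R <- sqrt(3) / 2
  v_ideal <- (sqrt(8 / 3) * R)^3 / (6 * sqrt(2))
  skew_oracle <- (v_ideal - V) / v_ideal
  expect_equal(volume_skew(tet), skew_oracle, tolerance = 1e-12)
  # both oracles happen to equal 1/2 exactly
  expect_equal(collapse_oracle, 0.5, tolerance = 1e-12)
  expect_equal(skew_oracle, 0.5, tolerance = 1e-12)
})

test_that("quality metrics are invariant under rigid motion and uniform scaling", {
  ball <- make_ball_image(radius_mm = 4, spacing = 0.5)
  mesh <- mesh_from_mask(ball$mask, 1.5, spacing = ball$spacing, origin = ball$origin)
  rigid <- similarity_transform(rotation = chma:::rotvec_to_quat(c(0.4, -0.1, 0.7)),
                                translation = c(5, -3, 2))
  scaled <- similarity_transform(scale = 2.7)
  for (t in list(rigid, scaled)) {
    m2 <- morph_mesh(mesh, t)
    expect_equal(tet_collapse(m2), tet_collapse(mesh), tolerance = 1e-9)
    expect_equal(volume_skew(m2), volume_skew(mesh), tolerance = 1e-9)
    expect_equal(aspect_ratio(m2), aspect_ratio(mesh), tolerance = 1e-9)
  }
  # uniform scale s multiplies every element volume by s^3 exactly
  expect_equal(element_volumes(morph_mesh(mesh, scaled)),
               element_volumes(mesh) * 2.7^3, tolerance = 1e-9)
})

test_that("morphing preserves connectivity and the identity map preserves vertices", {
  ball <- make_ball_image(radius_mm = 4, spacing = 0.5)
  mesh <- mesh_from_mask(ball$mask, 1.5, spacing = ball$spacing, origin = ball$origin)
  ident <- morph_mesh(mesh, identity_transform())
  expect_equal(ident$vertices, mesh$vertices, tolerance = 1e-12)
  expect_identical(ident$elements, mesh$elements)
  expect_equal(attr(ident, "n_inverted"), 0)
  set.seed(5)
  warp <- chma:::random_warp(c(-7, -7, -7), c(7, 7, 7), 8, 0.8)
  warped <- morph_mesh(mesh, warp)
  expect_identical(warped$elements, mesh$elements)
})

test_that("VTK mesh I/O round-trips vertices, elements and cell data", {
  ball <- make_ball_image(radius_mm = 3, spacing = 0.5)
  mesh <- mesh_from_mask(ball$mask, 1.5, spacing = ball$spacing, origin = ball$origin)
  path <- withr::local_tempfile(fileext = ".vtk")
  vals <- stats::runif(nrow(mesh$elements))
  write_mesh_vtk(mesh, path, cell_data = list(BVTV = vals))
  back <- read_mesh_vtk(path)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-12)
  expect_identical(back$elements, mesh$elements)
  expect_equal(attr(back, "cell_data")$BVTV, vals, tolerance = 1e-12)
})
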