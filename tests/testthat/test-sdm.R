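test_that("quaternion averaging matches the eigen-decomposition oracle", {
  qz <- function(th) c(cos(th / 2), 0, 0, sin(th / 2))
  # N copies of q -> q
  q <- chma:::quat_normalize(c(0.9, 0.1, -0.2, 0.3))
  expect_equal(average_quaternions(list(q, q, q)), q, tolerance = 1e-12)
  # sign invariance: {q, -q} represents the same rotation
  expect_equal(abs(sum(average_quaternions(list(q, -q)) * q)), 1, tolerance = 1e-9)
  # 0 and 90 degrees about z average to 45 degrees
  avg <- average_quaternions(list(qz(0), qz(pi / 2)))
  # oracle: principal eigenvector of the 4x4 accumulator, computed directly
  acc <- tcrossprod(qz(0)) + tcrossprod(qz(pi / 2))
  oracle <- eigen(acc, symmetric = TRUE)$vectors[, 1]
  if (oracle[1] < 0) oracle <- -oracle
  expect_equal(avg, oracle, tolerance = 1e-9)
  expect_equal(avg, qz(pi / 4), tolerance = 1e-6)
  expect_error(average_quaternions(list()), "at least one")
})

test_that("similarity averaging takes arithmetic means with a fixed centre", {
  ctr <- c(1, 2, 3)
  t1 <- similarity_transform(scale = 0.9, translation = c(2, 0, -1), center = ctr)
  t2 <- similarity_transform(scale = 1.1, translation = c(-2, 0, 1), center = ctr)
  avg <- average_similarity(list(t1, t2))
  expect_equal(avg$scale, 1.0)
  expect_equal(avg$translation, c(0, 0, 0))
  expect_equal(avg$center, ctr)
  expect_equal(average_similarity(list(t1, t1))$scale, t1$scale)
  t3 <- similarity_transform(center = c(9, 9, 9))
  expect_error(average_similarity(list(t1, t3)), "centre")
})

test_that("B-spline averaging is the elementwise mean and rejects grid mismatch", {
  m <- c(5, 5, 5)
  mk <- function(seed) {
    set.seed(seed)
    bspline_transform(c(0, 0, 0), c(4, 4, 4), m,
                      array(stats::rnorm(prod(m) * 3), c(m, 3)))
  }
  ts <- list(mk(1), mk(2), mk(3))
  avg <- average_bspline(ts)
  manual <- (ts[[1]]$displacements + ts[[2]]$displacements + ts[[3]]$displacements) / 3
  expect_equal(avg$displacements, manual, tolerance = 1e-12)
  # +u and -u cancel
  neg <- ts[[1]]; neg$displacements <- -neg$displacements
  expect_equal(max(abs(average_bspline(list(ts[[1]], neg))$displacements)), 0)
  other <- bspline_transform(c(0, 0, 0), c(4, 4, 4), c(6, 5, 5))
  expect_error(average_bspline(list(ts[[1]], other)), "mismatch")
})

test_that("B-spline inversion satisfies the composition residual bound", {
  # zero field inverts to zero
  z <- bspline_transform(c(0, 0, 0), c(10, 10, 10), c(6, 6, 6))
  expect_equal(max(abs(invert_bspline_approx(z)$displacements)), 0)

  # constant interior displacement inverts to its negative
  m <- c(7, 7, 7)
  disp <- array(0, c(m, 3)); disp[, , , 2] <- 1.2
  cst <- bspline_transform(c(0, 0, 0), c(10, 10, 10), m, disp)
  inv <- invert_bspline_approx(cst, tol = 0.05)
  centre_pt <- matrix(c(30, 30, 30), 1)
  expect_equal(as.numeric(chma:::bspline_displacement(inv, centre_pt)),
               c(0, -1.2, 0), tolerance = 0.05)

  # random smooth field (max ~2 mm, 20 mm grid): residual < 0.1 mm on probes
  set.seed(11)
  rnd <- bspline_transform(c(0, 0, 0), c(20, 20, 20), m,
                           array(stats::rnorm(prod(m) * 3, sd = 0.8), c(m, 3)))
  inv2 <- invert_bspline_approx(rnd, tol = 0.1)
  probe <- as.matrix(expand.grid(seq(25, 95, length.out = 10),
                                 seq(25, 95, length.out = 10),
                                 seq(25, 95, length.out = 10)))
  res <- sqrt(rowSums((transform_points(rnd, transform_points(inv2, probe)) - probe)^2))
  expect_lt(max(res), 0.1)
})

test_that("the canonical image of identical inputs is the input itself", {
  img <- small_bone()$image
  sdm <- build_canonical(list(img, img, img), n_iter = 1, rescale_factor = 4,
                         grid_spacing = 10)
  low <- rescale_by_factor(img, 4)
  aligned <- apply_transform(low, NULL, sdm$reference)
  expect_gte(dice(aligned, sdm$reference), 0.99)
  # voxelwise average stays within the input range
  expect_gte(min(sdm$reference$values), 0)
  expect_lte(max(sdm$reference$values), 1 + 1e-9)
})

test_that("the canonical bone of a translated pair sits midway between them", {
  img <- rescale_by_factor(small_bone()$image, 2)
  d <- c(2, 0, -1)
  a <- apply_transform(img, similarity_transform(translation = d), img)
  b <- apply_transform(img, similarity_transform(translation = -d), img)
  sdm <- build_canonical(list(a, b), n_iter = 1, rescale_factor = 2,
                         grid_spacing = 12)
  centroid <- function(im) {
    idx <- which(im$mask > 0, arr.ind = TRUE) - 1
    colMeans(sweep(sweep(idx, 2, im$spacing, "*"), 2, im$origin, "+"))
  }
  mid <- (centroid(rescale_by_factor(a, 2)) + centroid(rescale_by_factor(b, 2))) / 2
  expect_lt(max(abs(centroid(sdm$reference) - mid)),
            sdm$reference$spacing[1])
})

test_that("per-iteration diagnostics are recorded", {
  img <- small_bone()$image
  sdm <- build_canonical(list(img, img), n_iter = 1, rescale_factor = 4,
                         grid_spacing = 10)
  expect_equal(nrow(sdm$diagnostics), 1)
  expect_true(all(c("dice", "msd", "hausdorff") %in% names(sdm$diagnostics)))
  expect_error(build_canonical(list(img, img), n_iter = 0), "n_iter")
  expect_error(build_canonical(list(img)), "at least two")
})
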