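test_that("element-wise t matches the hand-computed pooled oracle", {
  # textbook pooled two-sample t for a = {1,2,3,4}, b = {3,4,5,6}:
  # means 2.5 / 4.5, pooled SS = 5 + 5, s2 = 10/6, t = -2 / sqrt(10/6 * 1/2)
  oracle <- -2 / sqrt((10 / 6) * (1 / 2))
  a <- matrix(c(1, 2, 3, 4), 4, 1)
  b <- matrix(c(3, 4, 5, 6), 4, 1)
  expect_equal(elementwise_ttest(a, b), oracle, tolerance = 1e-12)
  expect_equal(oracle, -2.19089023, tolerance = 1e-8)
  # cross-check against stats::t.test with pooled variance
  tt <- stats::t.test(a[, 1], b[, 1], var.equal = TRUE)
  expect_equal(elementwise_ttest(a, b), unname(tt$statistic), tolerance = 1e-12)
})

test_that("t statistics are antisymmetric and handle zero-variance elements", {
  set.seed(1)
  a <- matrix(stats::rnorm(50), 5)
  b <- matrix(stats::rnorm(50), 5)
  expect_equal(elementwise_ttest(a, b), -elementwise_ttest(b, a))
  expect_equal(elementwise_ttest(a, a), rep(0, 10))
  ca <- matrix(1, 3, 2); cb <- matrix(c(1, 1, 1, 2, 2, 2), 3, 2)
  t0 <- elementwise_ttest(ca, cb)
  expect_equal(t0[1], 0)          # equal constants
  expect_identical(t0[2], -Inf)   # unequal constants -> signed infinity
  expect_error(elementwise_ttest(a[1, , drop = FALSE], b), "at least two")
})

test_that("permutation threshold reduces to the univariate quantile and ignores duplicated columns", {
  set.seed(4)
  a <- matrix(stats::rnorm(8), 8, 1)
  b <- matrix(stats::rnorm(8), 8, 1)
  t1 <- fwer_threshold(a, b, n_perm = 2000, alpha = 0.05, seed = 3)
  # duplicated columns: max over identical columns equals the single column
  t2 <- fwer_threshold(cbind(a, a, a), cbind(b, b, b), n_perm = 2000,
                       alpha = 0.05, seed = 3)
  expect_equal(as.numeric(t1), as.numeric(t2))
  # univariate oracle: same permutations, |t| quantile computed directly
  expect_equal(as.numeric(t1),
               sort(attr(t1, "max_null"))[ceiling(0.95 * length(attr(t1, "max_null")))])
})

test_that("exhaustive enumeration is used for small samples and is seed-invariant", {
  set.seed(9)
  a <- matrix(stats::rnorm(9), 3)
  b <- matrix(stats::rnorm(9), 3)
  t1 <- fwer_threshold(a, b, n_perm = 1000, alpha = 0.05, seed = 1)
  t2 <- fwer_threshold(a, b, n_perm = 1000, alpha = 0.05, seed = 999)
  expect_true(attr(t1, "exhaustive"))
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_equal(attr(t1, "n_perm"), choose(6, 3))
})

test_that("empirical FWER stays at the nominal level on a small null simulation", {
  f <- simulate_fwer(n_per_group = 8, n_elements = 100, n_perm = 500,
                     alpha = 0.05, n_reps = 120, seed = 7)
  expect_lte(as.numeric(f), 0.05 + 2 * sqrt(0.05 * 0.95 / 120))
})

test_that("planted group differences are detected and localized", {
  set.seed(15)
  n <- 10; ne <- 200
  x <- matrix(stats::rnorm(2 * n * ne), 2 * n)
  planted <- 1:20                              # 10% of elements, 1.5 pooled-SD shift
  x[(n + 1):(2 * n), planted] <- x[(n + 1):(2 * n), planted] + 1.5
  a <- x[1:n, ]; b <- x[(n + 1):(2 * n), ]
  st <- compare_groups(a, b, n_perm = 2000, alpha = 0.05, seed = 2)
  # per-element power: a 1.5-SD shift is detected in >= 50% of planted
  # elements by the uncorrected test ...
  crit_unc <- stats::qt(0.975, df = 2 * n - 2)
  expect_gte(mean(abs(st$t[planted]) >= crit_unc), 0.5)
  # ... while the family-wise threshold trades power for error control:
  # everything it flags concentrates in the planted region
  expect_gt(sum(st$significant[planted]), 0)
  expect_gt(mean(st$significant[planted]), 10 * mean(st$significant[-planted]) + 1e-12)
  expect_gt(attr(st, "t_crit"), crit_unc)
})

test_that("PCA explains variance as constructed and is centring-invariant", {
  set.seed(6)
  base <- matrix(stats::rnorm(20), 1)
  # specimens along a single direction -> PC1 explains everything
  coefs <- stats::rnorm(6)
  m <- outer(coefs, as.numeric(base)) + 5
  p <- pca_elements(m)
  expect_gt(p$explained[1], 1 - 1e-9)
  # two orthogonal equal-variance modes -> 50/50 split
  d1 <- c(rep(1, 10), rep(0, 10)); d2 <- c(rep(0, 10), rep(1, 10))
  scores1 <- c(1, 1, 1, -1, -1, -1)
  scores2 <- c(1, -1, 0, 1, -1, 0) * sqrt(6) / 2   # orthogonal, equal norm
  m2 <- outer(scores1, d1) + outer(scores2, d2)
  p2 <- pca_elements(m2)
  expect_equal(p2$explained[1], 0.5, tolerance = 1e-9)
  expect_equal(p2$explained[2], 0.5, tolerance = 1e-9)
  # adding a constant changes nothing
  p3 <- pca_elements(m + 100)
  expect_equal(abs(p3$scores), abs(p$scores), tolerance = 1e-9)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_error(pca_elements(m[1:2, ]), "three")
})

test_that("percentile thresholding follows the linear-interpolation quantile convention", {
  expect_equal(which(percentile_threshold(1:10, 80)), c(9L, 10L))
  expect_equal(sum(percentile_threshold(rep(1, 10), 80)), 0)
  expect_equal(which(!percentile_threshold(1:10, 1e-6)), 1L)
  expect_error(percentile_threshold(1:10, 0), "strictly")
  expect_error(percentile_threshold(numeric(0), 50), "empty")
})

test_that("tidy and glance summarise comparison results", {
  set.seed(3)
  a <- matrix(stats::rnorm(40), 4)
  b <- matrix(stats::rnorm(40), 4)
  st <- compare_groups(a, b, n_perm = 200, alpha = 0.05, seed = 5)
  td <- generics::tidy(st)
  expect_s3_class(td, "data.frame")
  expect_named(td, c("element_id", "t", "mean_diff", "significant"))
  gl <- generics::glance(st)
  expect_equal(gl$n_elements, 10)
  expect_equal(gl$alpha, 0.05)
  expect_true(all((abs(st$t) >= gl$t_crit) == st$significant))
})
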