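# Element-wise group comparison across isotopological meshes: pooled-variance
# two-sample t statistics per element, a permutation max-|t| threshold for
# family-wise error rate (FWER) control, PCA over specimens, and percentile
# thresholding of mean fields.

as_group_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

# Pooled-variance two-sample t for every column, given group-A row sums over
# the pooled matrix. Vectorised so the same code serves the observed
# statistic and thousands of label permutations at once.
pooled_t_from_sums <- function(sa, n_a, tot, ss_tot, n_b) {
  sb <- sweep(-sa, 2, tot, "+")
  ma <- sa / n_a; mb <- sb / n_b
  ss_pool <- sweep(-(sa^2 / n_a + sb^2 / n_b), 2, ss_tot, "+")
  df <- n_a + n_b - 2
  s2 <- ss_pool / df
  s2[s2 < 0] <- 0
  se <- sqrt(s2 * (1 / n_a + 1 / n_b))
  num <- ma - mb
  t <- num / se
  t[se == 0 & abs(num) <= 1e-12] <- 0      # zero variance, equal means
  t[se == 0 & abs(num) > 1e-12] <- sign(num[se == 0 & abs(num) > 1e-12]) * Inf
  t
}

#' Element-wise pooled two-sample t statistics
#'
#' Independent-samples t test with pooled variance at every element.
#' Zero pooled variance with equal means yields t = 0; with unequal means,
#' a signed infinity (which always exceeds any finite threshold).
#'
#' @param a,b group submatrices, specimens in rows, elements in columns
#'   (>= 2 rows each).
#' @return numeric vector of t values (a minus b), one per element.
#' @export
elementwise_ttest <- function(a, b) {
  a <- as_group_matrix(a); b <- as_group_matrix(b)
  if (nrow(a) < 2 || nrow(b) < 2) stop("each group needs at least two specimens")
  if (ncol(a) != ncol(b)) stop("groups have different element counts")
  x <- rbind(a, b)
  tot <- colSums(x); ss_tot <- colSums(x^2)
  sa <- matrix(colSums(a), 1)
  as.numeric(pooled_t_from_sums(sa, nrow(a), tot, ss_tot, nrow(b)))
}

#' Permutation max-|t| threshold for FWER control
#'
#' Builds the null distribution of the maximum absolute element-wise t
#' statistic over random relabellings of the specimens and returns its
#' `1 - alpha` empirical quantile as the critical t value: any element with
#' `|t| >= t_crit` is significant with family-wise error controlled at
#' `alpha`. The observed labelling is included among the permutations
#' (standard max-statistic practice). When the total number of distinct
#' label assignments is at most `n_perm`, they are enumerated exhaustively
#' and the result does not depend on the seed.
#'
#' @param a,b group submatrices (specimens x elements).
#' @param n_perm number of permutations (>= 100).
#' @param alpha significance level.
#' @param seed RNG seed for the sampled permutations.
#' @return `t_crit`, with attributes `max_null` (the null maxima),
#'   `exhaustive` and `n_perm`.
#' @export
fwer_threshold <- function(a, b, n_perm = 10000, alpha = 0.05, seed = 1) {
  a <- as_group_matrix(a); b <- as_group_matrix(b)
  if (ncol(a) != ncol(b)) stop("groups have different element counts")
  n_a <- nrow(a); n_b <- nrow(b); n <- n_a + n_b
  if (n_a < 2 || n_b < 2) stop("each group needs at least two specimens")
  if (n_perm < 100) stop("n_perm must be >= 100")
  x <- rbind(a, b)
  tot <- colSums(x); ss_tot <- colSums(x^2)
  n_total <- choose(n, n_a)
  exhaustive <- n_total <= n_perm
  if (exhaustive) {
    combs <- utils::combn(n, n_a)
    P <- matrix(0, ncol(combs), n)
    P[cbind(rep(seq_len(ncol(combs)), each = n_a), as.integer(combs))] <- 1
  } else {
    P <- with_seed(seed, {
      t(vapply(seq_len(n_perm - 1L), function(i) {
        z <- numeric(n); z[sample.int(n, n_a)] <- 1; z
      }, numeric(n)))
    })
    P <- rbind(c(rep(1, n_a), rep(0, n_b)), P)  # observed labelling first
  }
  sa <- P %*% x
  tmat <- pooled_t_from_sums(sa, n_a, tot, ss_tot, n_b)
  max_null <- apply(abs(tmat), 1, max)
  k <- ceiling((1 - alpha) * length(max_null))
  if (k >= length(max_null)) {
    warning("too few distinct permutations for alpha = ", alpha,
            "; threshold is the largest null maximum")
    k <- length(max_null)
  }
  t_crit <- sort(max_null)[k]
  structure(t_crit, max_null = max_null, exhaustive = exhaustive,
            n_perm = nrow(P), alpha = alpha)
}

#' Element-wise group comparison with FWER control
#'
#' Convenience wrapper: observed t values, permutation threshold,
#' significance flags and group mean differences in one tidy result.
#'
#' @inheritParams fwer_threshold
#' @return An object of class `chma_stats`: data.frame with columns
#'   `element_id`, `t`, `mean_diff`, `significant`; the critical t, alpha
#'   and permutation count are attached as attributes (see
#'   [glance.chma_stats()]).
#' @export
compare_groups <- function(a, b, n_perm = 10000, alpha = 0.05, seed = 1) {
  t_obs <- elementwise_ttest(a, b)
  t_crit <- fwer_threshold(a, b, n_perm = n_perm, alpha = alpha, seed = seed)
  out <- data.frame(element_id = seq_along(t_obs), t = t_obs,
                    mean_diff = colMeans(as_group_matrix(a)) - colMeans(as_group_matrix(b)),
                    significant = abs(t_obs) >= as.numeric(t_crit))
  structure(out, class = c("chma_stats", "data.frame"),
            t_crit = as.numeric(t_crit), alpha = alpha,
            n_perm = attr(t_crit, "n_perm"), exhaustive = attr(t_crit, "exhaustive"),
            seed = seed)
}

#' @export
print.chma_stats <- function(x, ...) {
  cat("chma_stats:", nrow(x), "elements;", sum(x$significant),
      "significant at alpha", attr(x, "alpha"),
      "(t_crit", signif(attr(x, "t_crit"), 4), ",", attr(x, "n_perm"),
      "permutations)\n")
  invisible(x)
}

#' Tidy and summarise element-wise comparison results
#'
#' Broom-style accessors: `tidy()` returns the per-element table,
#' `glance()` a one-row summary (critical t, alpha, permutation count,
#' number of significant elements).
#'
#' @param x a `chma_stats` object.
#' @param ... unused.
#' @export
#' @importFrom generics tidy glance
#' @method tidy chma_stats
tidy.chma_stats <- function(x, ...) {
  data.frame(x)
}

#' @rdname tidy.chma_stats
#' @export
#' @method glance chma_stats
glance.chma_stats <- function(x, ...) {
  data.frame(t_crit = attr(x, "t_crit"), alpha = attr(x, "alpha"),
             n_perm = attr(x, "n_perm"), exhaustive = attr(x, "exhaustive"),
             n_elements = nrow(x), n_significant = sum(x$significant))
}

#' Monte-Carlo check of the family-wise error rate
#'
#' Simulates the global null — two groups drawn from the same iid Gaussian
#' at every element — and reports the fraction of replicates in which the
#' permutation max-|t| procedure flags at least one element. Under a valid
#' procedure this empirical FWER stays at or below `alpha` up to binomial
#' error.
#'
#' @param n_per_group specimens per group.
#' @param n_elements elements per specimen.
#' @param n_perm permutations per replicate.
#' @param alpha significance level.
#' @param n_reps Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return empirical FWER, with attributes `se` (binomial standard error)
#'   and `n_reps`.
#' @export
simulate_fwer <- function(n_per_group = 10, n_elements = 500, n_perm = 2000,
                          alpha = 0.05, n_reps = 500, seed = 1) {
  hits <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      x <- matrix(stats::rnorm(2 * n_per_group * n_elements), 2 * n_per_group)
      a <- x[seq_len(n_per_group), , drop = FALSE]
      b <- x[n_per_group + seq_len(n_per_group), , drop = FALSE]
      t_crit <- fwer_threshold(a, b, n_perm = n_perm, alpha = alpha,
                               seed = seed + r)
      any(abs(elementwise_ttest(a, b)) >= as.numeric(t_crit))
    }, logical(1))
  })
  fwer <- mean(hits)
  structure(fwer, se = sqrt(alpha * (1 - alpha) / n_reps), n_reps = n_reps)
}

#' PCA of element fields across specimens
#'
#' Column-mean-centred principal component analysis (via SVD) of the
#' specimens-by-elements matrix; the sign of each component is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param m matrix, specimens in rows (>= 3), elements in columns.
#' @param k number of components to keep (default all).
#' @return list with `scores` (specimens x k), `explained` (variance
#'   fractions, non-increasing) and `loadings`.
#' @export
pca_elements <- function(m, k = NULL) {
  m <- as_group_matrix(m)
  if (nrow(m) < 3) stop("PCA needs at least three specimens")
  centred <- scale(m, center = TRUE, scale = FALSE)
  if (max(abs(centred)) <= 1e-300) stop("rank-zero matrix")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- k %||% ncol(p$x)
  k <- min(k, ncol(p$x))
  flip <- vapply(seq_len(k), function(j) {
    l <- p$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(p$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(p$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, explained = expl[seq_len(k)], loadings = loadings)
}

#' Percentile threshold of an element field
#'
#' Flags elements whose value lies strictly above the `pct` percentile of
#' the field (quantile by linear interpolation between order statistics,
#' the R default); used e.g. to extract high-density structures from a mean
#' rBVTV field at the 80th percentile.
#'
#' @param field an `element_field` or numeric vector.
#' @param pct percentile in (0, 100).
#' @return logical vector, one flag per element.
#' @export
percentile_threshold <- function(field, pct) {
  v <- if (is.data.frame(field)) field$value else as.numeric(field)
  if (!length(v)) stop("empty field")
  if (pct <= 0 || pct >= 100) stop("pct must be strictly between 0 and 100")
  q <- stats::quantile(v, pct / 100, type = 7, names = FALSE)
  v > q
}
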