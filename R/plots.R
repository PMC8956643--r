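# ggplot2 helpers for the tabular outputs of a run.

#' Plot canonical-model convergence diagnostics
#'
#' Mean surface distance and Dice coefficient between consecutive
#' references per model iteration.
#'
#' @param sdm an `sdm_state` from [build_canonical()].
#' @export
plot_sdm_convergence <- function(sdm) {
  d <- sdm$diagnostics
  long <- rbind(data.frame(iteration = d$iteration, metric = "MSD (mm)", value = d$msd),
                data.frame(iteration = d$iteration, metric = "1 - Dice", value = 1 - d$dice))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "model iteration", y = NULL,
                  title = "Canonical model convergence") +
    ggplot2::theme_minimal()
}

#' Plot PCA scores of element fields
#'
#' @param pca result of [pca_elements()].
#' @param groups group label per specimen.
#' @param components which two components to show.
#' @export
plot_pca_scores <- function(pca, groups, components = c(1, 2)) {
  df <- data.frame(x = pca$scores[, components[1]],
                   y = pca$scores[, components[2]],
                   group = groups)
  lab <- function(k) sprintf("PC%d (%.1f%%)", k, 100 * pca$explained[k])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(components[1]), y = lab(components[2]),
                  title = "PCA of element fields") +
    ggplot2::theme_minimal()
}

#' Histogram of element-wise t values with the FWER threshold
#'
#' @param stats a `chma_stats` result from [compare_groups()].
#' @export
plot_t_distribution <- function(stats) {
  tc <- attr(stats, "t_crit")
  df <- data.frame(t = stats$t[is.finite(stats$t)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::geom_vline(xintercept = c(-tc, tc), linetype = "dashed") +
    ggplot2::labs(x = "element-wise t", y = "elements",
                  title = sprintf("Element-wise t values (critical |t| = %.2f)", tc)) +
    ggplot2::theme_minimal()
}
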