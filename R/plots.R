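# ggplot2 displays for the main result types.

#' Plot an anchored signal profile
#'
#' Line plot of a profile from [aggregate_around_anchors()] or
#' [pmd_boundary_profiles()], offsets on the x axis (kb), with a ribbon of
#' +/- 1 SD across anchors when available.
#'
#' @param profile Profile tibble; an optional `track` column gives one line
#'   per track.
#' @return A ggplot object.
#' @export
plot_boundary_profile <- function(profile) {
  profile <- profile |>
    mutate(offset_kb = (.data$offset_start + .data$offset_end) / 2000)
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$offset_kb, y = .data$mean))
  if ("track" %in% names(profile)) {
    p <- p + ggplot2::aes(colour = .data$track)
  }
  p +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from boundary (kb, domain interior > 0)",
                  y = "mean signal (flank-normalized)")
}

#' Plot a three-Gaussian mixture fit over the data
#'
#' Histogram of the values with the fitted weighted component densities and,
#' optionally, the crossover thresholds.
#'
#' @param object A `mixfit3` object.
#' @param values The data the mixture was fitted to.
#' @param thresholds Optional one-row tibble from [crossover_points()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mixfit3
#' @export
autoplot.mixfit3 <- function(object, values, thresholds = NULL, bins = 100,
                             ...) {
  grid <- seq(min(values), max(values), length.out = 512)
  dens <- purrr::map_dfr(1:3, function(k) {
    tibble(component = factor(k), x = grid,
           density = object$weights[k] *
             stats::dnorm(grid, object$means[k], object$sds[k]))
  })
  p <- ggplot2::ggplot(tibble(x = values), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey70") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = "log2 fold change", y = "density")
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(thresholds$lower, thresholds$upper),
      linetype = "dashed")
  }
  p
}

#' Plot co-accessibility correlations against the calling threshold
#'
#' Histogram of pair correlations with the permutation-derived threshold.
#'
#' @param pairs Pair tibble with a `correlation` column.
#' @param threshold Calling threshold from [permutation_threshold()].
#' @return A ggplot object.
#' @export
plot_pair_correlations <- function(pairs, threshold = NULL) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$correlation)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey80", colour = "grey60") +
    ggplot2::labs(x = "phi (co-accessibility)", y = "pairs")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                                 colour = "red3")
  }
  p
}
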