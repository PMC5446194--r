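#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an occupancy track along the genome
#'
#' @param object An `occupancy_track`.
#' @param ... Unused.
#' @return A ggplot: per-window log2(ChIP/Input) against position,
#'   facetted by chromosome.
#' @method autoplot occupancy_track
#' @export
autoplot.occupancy_track <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$log2_ratio)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = "log2(ChIP/Input)")
}

#' Plot the Input-predictability fit
#'
#' @param object An `input_fit`, ideally after [partition_outliers()].
#' @param ... Unused.
#' @return A ggplot: ChIP against Input signal with the least-squares line,
#'   coloured by outlier label.
#' @method autoplot input_fit
#' @export
autoplot.input_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$input, y = .data$chip,
                               colour = .data$label)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::scale_colour_manual(values = c(depleted = "#2e7d32",
                                            neutral = "grey40",
                                            enriched = "#6a1b9a")) +
    ggplot2::labs(x = "Input signal", y = "ChIP signal",
                  subtitle = sprintf("R² = %.3f", object$r_squared))
}

#' Plot an aggregate meta-profile
#'
#' @param object A `profile_matrix`.
#' @param ... Unused.
#' @return A ggplot of the aggregate per-bin signal against distance from
#'   the anchor.
#' @method autoplot profile_matrix
#' @export
autoplot.profile_matrix <- function(object, ...) {
  df <- tibble::tibble(offset = object$bin_mid, value = object$aggregate)
  ylab <- if (object$mode == "density") "methylation density per kb" else "signal"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from anchor (bp)", y = ylab)
}

#' Heatmap of the scale-by-score segment summary
#'
#' @param object A `scale_score_summary`.
#' @param fill Column to map to fill (default `"n"`; any `mean_*`
#'   annotation column works).
#' @param ... Unused.
#' @return A ggplot tile heatmap: scale on x, score bin on y.
#' @method autoplot scale_score_summary
#' @export
autoplot.scale_score_summary <- function(object, fill = "n", ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$scale_bp),
                               y = .data$score_bin,
                               fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "scale (bp)", y = "enrichment score bin", fill = fill)
}

#' MA-style plot of a differential-expression result
#'
#' @param object An `nb_de` tibble, optionally classified.
#' @param ... Unused.
#' @return A ggplot of log2 fold change against mean expression, coloured
#'   by class when present.
#' @method autoplot nb_de
#' @export
autoplot.nb_de <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$base_mean, y = .data$log2fc)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean normalised count", y = "log2 fold change")
  if ("class" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$class),
                            size = 0.5, alpha = 0.6) +
      ggplot2::scale_colour_manual(values = c(
        up = "#6a1b9a", down = "#2e7d32", unchanged = "grey30",
        other = "grey70", filtered = "grey90"))
  } else {
    p + ggplot2::geom_point(size = 0.5, alpha = 0.6)
  }
}
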