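#' Plot a background distribution with its Weibull fit
#'
#' Histogram of the replicate intersections-per-bp values with the
#' fitted Weibull density overlaid (when the fit succeeded).
#'
#' @param object A `background_dist` from [build_background()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.background_dist <- function(object, ...) {
  df <- tibble::tibble(value = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "intersections per bp (background)", y = "density",
                  subtitle = object$fit_note) +
    ggplot2::theme_minimal()
  if (is.finite(object$shape)) {
    p <- p + ggplot2::stat_function(
      fun = stats::dweibull,
      args = list(shape = object$shape, scale = object$scale),
      colour = "firebrick", linewidth = 0.8
    )
  }
  p
}

#' Dot plot of enrichment results
#'
#' Traits on the y axis, percent enrichment on the x axis, one panel per
#' annotation; points sized by `-log10(q)` and filled by whether they
#' clear the FDR threshold.
#'
#' @param results A tibble from [run_enrichment()].
#' @param alpha FDR threshold used for the fill (default 0.05).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, alpha = 0.05) {
  stopifnot(all(c("trait_id", "annot_id", "I_percent", "q") %in%
                  names(results)))
  ggplot2::ggplot(
    results,
    ggplot2::aes(x = .data$I_percent,
                 y = stats::reorder(.data$trait_id, .data$I_percent))
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = -log10(.data$q),
                                     colour = .data$q < alpha)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40"),
                                 name = sprintf("q < %.2g", alpha)) +
    ggplot2::scale_size_continuous(name = "-log10(q)") +
    ggplot2::facet_wrap(ggplot2::vars(.data$annot_id)) +
    ggplot2::labs(x = "overlap enrichment I (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of category meta-analysis results
#'
#' @param meta A tibble from [meta_batch()].
#' @param alpha FDR threshold for highlighting (default 0.05).
#' @return A ggplot object.
#' @export
plot_meta <- function(meta, alpha = 0.05) {
  stopifnot(all(c("category", "mu_hat", "se_mu", "q") %in% names(meta)))
  ggplot2::ggplot(meta, ggplot2::aes(x = .data$mu_hat, y = .data$category)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mu_hat - 1.96 * .data$se_mu,
                   xmax = .data$mu_hat + 1.96 * .data$se_mu),
      height = 0.2, colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$q < alpha), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40"),
                                 name = sprintf("q < %.2g", alpha)) +
    ggplot2::labs(x = "summary estimate", y = NULL) +
    ggplot2::theme_minimal()
}
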