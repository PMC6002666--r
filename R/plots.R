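#' Plot a fitted rarefaction model over its median points
#'
#' Medians are drawn as points, the fitted curve as a solid line, and the
#' extrapolated asymptote (core-genome size or long-run new-gene rate) as
#' a dashed horizontal line.
#'
#' @param object A `decay_fit` or `heaps_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.decay_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble(n = seq(min(pts$n), max(pts$n), length.out = 200))
  grid$fit <- predict(object, grid$n)
  lab <- if (object$model == "core_decay") "Core genes" else "New genes"
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$n, y = .data$median)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$asymptote, linetype = "dashed") +
    ggplot2::geom_point(shape = 15, colour = "darkorange", size = 2) +
    ggplot2::labs(
      x = "Number of genomes (n)", y = paste(lab, "(median)"),
      title = sprintf("%s: %s = %.0f +/- %.0f, adj R2 = %.4f",
                      lab, object$asymptote_name, object$asymptote,
                      object$se_asymptote, object$adj_r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.decay_fit
#' @exportS3Method ggplot2::autoplot
autoplot.heaps_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble(n = seq(min(pts$n), max(pts$n), length.out = 200))
  grid$fit <- predict(object, grid$n)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$n, y = .data$median)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::geom_point(shape = 15, colour = "darkorange", size = 2) +
    ggplot2::labs(
      x = "Number of genomes (n)", y = "New genes (median)",
      title = sprintf("Heaps power law: alpha = %.2f +/- %.2f (%s pan-genome)",
                      object$alpha, object$se_alpha, object$verdict)
    ) +
    ggplot2::theme_minimal()
}

#' Plot median rarefaction curves
#'
#' @param curve Curve tibble from [summarize_curve()].
#' @return A ggplot object faceted by curve kind.
#' @export
plot_rarefaction <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n, y = .data$median)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(shape = 15, colour = "darkorange", size = 2) +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "Number of genomes (n)", y = "Median gene count") +
    ggplot2::theme_minimal()
}
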