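#' Plot a power-law richness fit
#'
#' Log-log scatter of observed richness against summed abundance with the
#' fitted line `log10 d = log10 c + gamma * log10 A`.
#'
#' @param object A `power_law_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$A), y = log10(.data$d_obs))) +
    ggplot2::geom_point(alpha = 0.5, colour = "steelblue") +
    ggplot2::geom_abline(intercept = log10(object$c), slope = object$gamma,
                         colour = "firebrick") +
    ggplot2::labs(x = "log10 summed abundance (TPM)",
                  y = "log10 unique variants",
                  title = sprintf("d = %.3g * A^%.3f (r² = %.3f)",
                                  object$c, object$gamma, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a delta-deviation distribution
#'
#' Kernel density of log10 delta; zero marks richness exactly as expected
#' from abundance, negative values variant-poor taxa, positive values
#' variant-rich taxa.
#'
#' @param object A `delta_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot delta_distribution
#' @export
autoplot.delta_distribution <- function(object, ...) {
  ggplot2::ggplot(object$kde, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "log10 delta (observed / expected richness)",
                  y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a per-residue enrichment result
#'
#' Mean frequency difference (group A minus group B) per residue, coloured
#' by classification.
#'
#' @param object An `aa_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot aa_enrichment
#' @export
autoplot.aa_enrichment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$diff <- df$mean_a - df$mean_b
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$diff,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(enriched = "firebrick",
                                          depleted = "steelblue",
                                          same = "grey70")) +
    ggplot2::labs(x = "residue", y = "mean frequency difference (A - B)") +
    ggplot2::theme_minimal()
}

#' Plot a ka/ks screen
#'
#' Per-pair dN/dS ratios on a log scale, coloured by selection regime;
#' the shaded band is the neutral zone.
#'
#' @param object A `kaks_screen` tibble.
#' @param neutral_band Band drawn on the plot (default `c(0.9, 1.1)`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kaks_screen
#' @export
autoplot.kaks_screen <- function(object, neutral_band = c(0.9, 1.1), ...) {
  df <- tibble::as_tibble(object)
  df <- df[is.finite(df$ratio) & df$ratio > 0, , drop = FALSE]
  df$pair <- paste(df$id_a, df$id_b, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$ratio,
                                   colour = .data$regime)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = neutral_band[1], ymax = neutral_band[2],
                      alpha = 0.15, fill = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(purifying = "darkgreen",
                                            neutral = "black",
                                            positive = "firebrick")) +
    ggplot2::labs(x = NULL, y = "ka/ks (dN/dS)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
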