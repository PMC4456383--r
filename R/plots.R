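#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point geom_rect
#'   geom_hline facet_grid labs theme_minimal autoplot
NULL

#' Plot a strain composition profile
#'
#' Bar chart of the per-strain mode estimates with the number of
#' diagnostic sites used; the unexplained residual is shown in the
#' subtitle.
#'
#' @param object A [strain_composition()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strain_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$strain, y = .data$estimate)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "estimated frequency",
         title = "Strain composition (mode of diagnostic-site frequencies)",
         subtitle = sprintf("unexplained residual: %.3f",
                            attr(object, "residual"))) +
    theme_minimal()
}

#' Plot sliding-window diversity statistics
#'
#' Theta_W, pi (per bp) and Tajima's D along each contig.
#'
#' @param object A [sliding_windows()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.window_stats <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("contig", "start", "theta_w", "theta_pi",
                          "tajimas_d")],
    c("theta_w", "theta_pi", "tajimas_d"),
    names_to = "statistic", values_to = "value")
  ggplot(long, aes(x = .data$start / 1000, y = .data$value)) +
    geom_line(colour = "grey30") +
    facet_grid(statistic ~ contig, scales = "free_y") +
    labs(x = "window start (kb)", y = NULL,
         title = "Windowed population-genetic statistics") +
    theme_minimal()
}

#' Plot CNV calls over the rank-variance track
#'
#' Per-position across-sample rank variance with called regions
#' highlighted.
#'
#' @param object A [detect_cnv()] result.
#' @param thin Keep every `thin`-th position of the variance track for
#'   plotting (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cnv_calls <- function(object, thin = 10, ...) {
  rv <- attr(object, "rank_var")
  rv <- rv[seq(1, nrow(rv), by = thin), ]
  p <- ggplot(rv, aes(x = .data$pos / 1000, y = .data$rank_var)) +
    geom_point(size = 0.2, alpha = 0.4) +
    facet_grid(. ~ contig, scales = "free_x", space = "free_x") +
    labs(x = "position (kb)", y = "rank variance",
         title = "Coverage-rank variance and CNV calls") +
    theme_minimal()
  if (nrow(object)) {
    p <- p + geom_rect(
      data = as_tibble(object)[, c("contig", "start", "end")],
      aes(xmin = .data$start / 1000, xmax = .data$end / 1000,
          ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.25)
  }
  p
}
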