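#' Cost-effectiveness plane of bootstrap replicates
#'
#' Scatter of incremental effect (x) against incremental cost (y), one
#' point per bootstrap replicate, with the origin's axes drawn so the four
#' quadrants are visible. Facetted by timepoint; filter the replicates to
#' one outcome and perspective before plotting or let the function facet
#' over them too.
#'
#' @param replicates A `cea_replicates` tibble.
#' @param lambda Optional willingness-to-pay threshold; when supplied, the
#'   line `cost = lambda x effect` is drawn (replicates below it are
#'   cost-effective at that threshold).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(replicates, lambda = NULL) {
  p <- ggplot2::ggplot(
    as_tibble(replicates),
    ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.25, size = 0.8, colour = "#2c7fb8") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$perspective),
      cols = ggplot2::vars(.data$outcome, .data$timepoint),
      scales = "free_x"
    ) +
    ggplot2::labs(
      x = "Incremental effect (intervention - control)",
      y = "Incremental cost (USD)",
      title = "Cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(lambda)) {
    p <- p + ggplot2::geom_abline(slope = lambda, intercept = 0,
                                  linetype = "dashed", colour = "grey30")
  }
  p
}

#' @describeIn plot_ce_plane autoplot method for replicate tables.
#' @param object A `cea_replicates` tibble.
#' @param ... Passed to `plot_ce_plane()`.
#' @export
autoplot.cea_replicates <- function(object, ...) plot_ce_plane(object, ...)

#' Plot a cost-effectiveness acceptability curve
#'
#' Probability of cost-effectiveness against willingness to pay, one line
#' per outcome, facetted by timepoint and perspective.
#'
#' @param object A `ceac_curve` tibble from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$lambda, y = .data$probability,
                 colour = .data$outcome)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$perspective),
      cols = ggplot2::vars(.data$timepoint)
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (USD per unit effect)",
      y = "Probability cost-effective",
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
}
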