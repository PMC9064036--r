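#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a bias-corrected generation-time distribution
#'
#' Bar plot of the corrected probability mass over generation time, with
#' the uncorrected (raw count) distribution overlaid as a step outline
#' for comparison.
#'
#' @param object A `gt_dist` tibble from [estimate_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gt_dist <- function(object, ...) {
  raw <- object$count / sum(object$count)
  df <- tibble::as_tibble(object)
  df$raw <- raw
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau_h)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$probability),
                      fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = .data$raw),
                       direction = "mid", colour = "grey30") +
    ggplot2::labs(
      x = "generation time (h)",
      y = "probability",
      title = "Generation-time distribution",
      subtitle = "bars: censoring-corrected; step line: raw"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted growth kinetic over the replicate data
#'
#' Replicate growth rates against concentration on a log axis with the
#' fitted model curve. Zero-concentration points are shown at the left
#' axis edge.
#'
#' @param object A `kinetic_fit`.
#' @param n_curve Points on the fitted curve (default 200).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetic_fit <- function(object, n_curve = 200, ...) {
  obs <- object$data
  pos <- obs$concentration[obs$concentration > 0]
  lo <- min(pos) / 2
  hi <- max(pos) * 1.2
  grid <- exp(seq(log(lo), log(hi), length.out = n_curve))
  curve <- tibble::tibble(
    concentration = grid,
    mu = predict(object, grid)
  )
  plot_obs <- dplyr::mutate(
    obs, concentration = pmax(.data$concentration, lo)
  )
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data$concentration, y = .data$mu)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(data = plot_obs, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "substrate concentration (mmol/L)",
      y = expression(mu ~ (h^-1)),
      title = sprintf("'%s' kinetic fit (%d replicates)",
                      object$model, object$n_obs)
    ) +
    ggplot2::theme_minimal()
}

#' Heterogeneity plot: variance against mean generation time
#'
#' One point per analyzed experiment, coloured by concentration — the
#' standard display of growth heterogeneity, where a positive
#' correlation indicates that slow-growing populations are also noisier.
#'
#' @param results The `results` tibble of [run_analysis()], or its
#'   `heterogeneity` element.
#' @return A ggplot object.
#' @export
plot_heterogeneity <- function(results) {
  df <- dplyr::filter(results, !is.na(.data$mean_tau_h))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_tau_h, y = .data$var_tau_h2,
    colour = log10(pmax(.data$concentration_mmol_per_L, 1e-3))
  )) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_viridis_c(name = "log10 c (mmol/L)") +
    ggplot2::labs(
      x = "mean generation time (h)",
      y = expression(variance ~ (h^2)),
      title = "Cell-to-cell heterogeneity"
    ) +
    ggplot2::theme_minimal()
}
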