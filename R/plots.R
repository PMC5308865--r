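#' Plot a temperature sweep
#'
#' Four-panel summary of a sweep table from [mc_temperature_sweep()] or
#' [abm_temperature_sweep()]: the huddling order parameter, pup flow (the
#' fluctuation/heat-capacity analog), the mean number of groups, and the
#' mean body temperature, each against ambient temperature. A vertical guide
#' marks the preferred body temperature.
#'
#' @param sweep A sweep tibble (columns `t_a`, `pup_flow`, `groups_mean`,
#'   `t_b_mean`, and `h_mean` or `huddling`).
#' @param t_p Preferred body temperature to mark (default 37).
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep, t_p = 37) {
  hud <- if ("h_mean" %in% names(sweep)) "h_mean" else "huddling"
  long <- sweep |>
    dplyr::select(dplyr::all_of(c("t_a", hud, "pup_flow", "groups_mean",
                                  "t_b_mean"))) |>
    tidyr::pivot_longer(-"t_a", names_to = "metric") |>
    dplyr::group_by(.data$t_a, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_a, .data$value)) +
    ggplot2::geom_vline(xintercept = t_p, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(T[A] ~ (degree * C)), y = NULL)
}

#' Plot an evolutionary trace
#'
#' The second-weakest metabolic rate `g_min` over generations, the classic
#' stasis-and-avalanche picture; detected avalanches are shaded.
#'
#' @param object An `evolution_trace` from [evolve()].
#' @param threshold Avalanche threshold passed to [detect_avalanches()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evolution_trace <- function(object, threshold = 0.5, ...) {
  av <- detect_avalanches(object, threshold)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$generation, .data$g_min))
  if (nrow(av) > 0) {
    p <- p + ggplot2::geom_rect(
      data = av,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85"
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "generation", y = expression(G[min]))
}
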