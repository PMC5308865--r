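#' Locate the huddling phase transition in a temperature sweep
#'
#' The transition region is bracketed by the temperatures at which the
#' replicate-averaged huddling metric first drops below 80% and below 20% of
#' its maximum (scanning from cold to warm, with linear interpolation between
#' grid points). The fluctuation peak of a second-order transition is
#' expected to fall between these crossings.
#'
#' @param sweep A sweep tibble from [mc_temperature_sweep()] or
#'   [abm_temperature_sweep()] (column `h_mean` or `huddling`, plus `t_a`).
#' @return A one-row tibble with `t_80`, `t_20` (degrees C) and `h_max`.
#'   A crossing that never happens is `NA`.
#' @export
transition_region <- function(sweep) {
  hud <- if ("h_mean" %in% names(sweep)) "h_mean" else "huddling"
  avg <- sweep |>
    dplyr::group_by(.data$t_a) |>
    dplyr::summarise(h = mean(.data[[hud]]), .groups = "drop") |>
    dplyr::arrange(.data$t_a)
  h_max <- max(avg$h)
  cross <- function(level) {
    below <- which(avg$h < level)
    if (length(below) == 0) return(NA_real_)
    i <- below[1]
    if (i == 1) return(avg$t_a[1])
    # linear interpolation on the segment where h falls through the level
    t0 <- avg$t_a[i - 1]; t1 <- avg$t_a[i]
    h0 <- avg$h[i - 1]; h1 <- avg$h[i]
    t0 + (h0 - level) / (h0 - h1) * (t1 - t0)
  }
  tibble(t_80 = cross(0.8 * h_max), t_20 = cross(0.2 * h_max), h_max = h_max)
}
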