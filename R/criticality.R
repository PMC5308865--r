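#' Histogram of the second-weakest metabolic rate
#'
#' Equal-width bins over `(range[1], range[2]]` of the per-generation `g_min`
#' values (the largest metabolic rate outside the weakest individual). The
#' power-law form of this distribution is the signature of self-organised
#' criticality in the evolved huddle.
#'
#' @param trace An `evolution_trace` (or any data frame with a `g_min`
#'   column).
#' @param n_bins Number of bins (default 30; must be >= 3).
#' @param range Support of the histogram (default `c(0, 5)`, the metabolic
#'   sampling range).
#' @param log_bins Use logarithmically spaced bin edges instead of equal
#'   widths.
#' @return A tibble with columns `bin`, `centre`, `count`; counts sum to the
#'   number of generations with `g_min` inside the range.
#' @export
gmin_histogram <- function(trace, n_bins = 30, range = c(0, 5),
                           log_bins = FALSE) {
  if (n_bins < 3) abort("`n_bins` must be at least 3.")
  stopifnot("g_min" %in% names(trace))
  x <- trace$g_min
  x <- x[x > range[1] & x <= range[2]]
  breaks <- if (log_bins) {
    lo <- max(range[1], min(x, range[2]) / 2)
    exp(seq(log(lo), log(range[2]), length.out = n_bins + 1))
  } else {
    seq(range[1], range[2], length.out = n_bins + 1)
  }
  if (log_bins) x <- x[x > breaks[1]]
  idx <- findInterval(x, breaks, left.open = TRUE, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  tibble(
    bin = seq_len(n_bins),
    centre = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
    width = diff(breaks),
    count = counts
  )
}

#' Power-law fit to a histogram by log-log regression
#'
#' Ordinary least squares of `log(count)` on `log(centre)` over the non-empty
#' bins: the model `log H = m log G + c`, i.e. `H` proportional to `G^m`.
#' With fewer than three non-empty bins the fit is refused (a condition that
#' arises for evolution near or above the preferred temperature, where the
#' distribution is not scale-free).
#'
#' @param h A histogram tibble from [gmin_histogram()] (columns `centre`,
#'   `count`, optionally `width`).
#' @param density Regress `log(count / width)` instead of `log(count)`.
#'   Irrelevant for equal-width bins (the slope is unchanged and only the
#'   intercept shifts) but required for the exponent to keep its density
#'   meaning under logarithmic binning.
#' @return An object of class `powerlaw_fit` with elements `m` (slope, the
#'   power-law exponent), `c` (intercept), `r2`, `bins_used`, and the fitted
#'   data. Supports [tidy()], [glance()], `print()` and
#'   [ggplot2::autoplot()].
#' @examples
#' h <- tibble::tibble(centre = 1:10, count = round(1000 * (1:10)^-2))
#' fit_power_law(h)
#' @export
fit_power_law <- function(h, density = FALSE) {
  stopifnot(all(c("centre", "count") %in% names(h)))
  keep <- h$count > 0
  if (sum(keep) < 3) {
    abort("power-law fit refused: fewer than 3 non-empty bins.",
          class = "huddlesoc_fit_refused")
  }
  lx <- log(h$centre[keep])
  y <- h$count[keep]
  if (density) {
    stopifnot("width" %in% names(h))
    y <- y / h$width[keep]
  }
  ly <- log(y)
  fit <- lm(ly ~ lx)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(
    m = unname(coef(fit)[2]),
    c = unname(coef(fit)[1]),
    r2 = r2,
    bins_used = sum(keep),
    data = tibble(centre = h$centre[keep], count = h$count[keep])
  ), class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Power-law fit: log H = m log G + c\n")
  cat(sprintf("  exponent m = %.3f, intercept c = %.3f\n", x$m, x$c))
  cat(sprintf("  r^2 = %.3f over %d non-empty bins\n", x$r2, x$bins_used))
  invisible(x)
}

#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = c("log_slope", "log_intercept"), estimate = c(x$m, x$c))
}

#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(m = x$m, c = x$c, r.squared = x$r2, bins_used = x$bins_used)
}

#' Log-log plot of a power-law fit
#'
#' @param object A `powerlaw_fit` from [fit_power_law()].
#' @param ... Unused.
#' @return A ggplot of the non-empty histogram bins with the fitted line,
#'   both axes on log scale.
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$centre, .data$count)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      ggplot2::aes(y = exp(object$c) * .data$centre^object$m),
      colour = "red"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(G[min]), y = expression(H(G[min])),
                  title = sprintf("m = %.2f, r² = %.2f",
                                  object$m, object$r2))
}

#' Segment avalanches in an evolutionary trace
#'
#' An avalanche is a maximal run of consecutive generations during which the
#' second-weakest metabolic rate exceeds a threshold, i.e. a burst
#' interrupting the stasis-near-zero regime.
#'
#' @param trace An `evolution_trace` (needs columns `generation`, `g_min`).
#' @param threshold Onset threshold on `g_min` (default 0.5, a tenth of the
#'   metabolic sampling range; the stasis regime sits well below it).
#' @return A tibble with one row per avalanche: `start`, `end`, `duration`,
#'   `peak`.
#' @export
detect_avalanches <- function(trace, threshold = 0.5) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  stopifnot(all(c("generation", "g_min") %in% names(trace)))
  above <- trace$g_min > threshold
  if (!any(above)) {
    return(tibble(start = integer(), end = integer(), duration = integer(),
                  peak = numeric()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  purrr::map2_dfr(starts[keep], ends[keep], function(s, e) {
    tibble(
      start = trace$generation[s],
      end = trace$generation[e],
      duration = e - s + 1L,
      peak = max(trace$g_min[s:e])
    )
  })
}

#' Power-law exponent as a function of ambient temperature
#'
#' Fits the `g_min` histogram of each temperature's evolutionary trace. A
#' temperature's fit is flagged not-OK when the fit is refused (fewer than 3
#' non-empty bins) or explains less than `r2_min` of the log-log variance —
#' the regime expected as the ambient temperature approaches the preferred
#' body temperature.
#'
#' @param traces A data frame with columns `t_a` and `g_min` (rows from all
#'   traces stacked), or a named list of traces with names giving `t_a`.
#' @param n_bins,range Passed to [gmin_histogram()].
#' @param r2_min Minimum r-squared for `fit_ok` (default 0.8).
#' @return A tibble with one row per temperature: `t_a`, `m`, `c`, `r2`,
#'   `bins_used`, `fit_ok`.
#' @export
exponent_sweep <- function(traces, n_bins = 30, range = c(0, 5),
                           r2_min = 0.8) {
  if (is.list(traces) && !is.data.frame(traces)) {
    stopifnot(!is.null(names(traces)))
    traces <- purrr::imap_dfr(traces, function(tr, nm) {
      tibble(t_a = as.numeric(nm), g_min = tr$g_min)
    })
  }
  stopifnot(all(c("t_a", "g_min") %in% names(traces)))
  traces |>
    dplyr::group_by(.data$t_a) |>
    dplyr::group_modify(function(d, key) {
      fit <- tryCatch(
        fit_power_law(gmin_histogram(d, n_bins = n_bins, range = range)),
        huddlesoc_fit_refused = function(e) NULL
      )
      if (is.null(fit)) {
        tibble(m = NA_real_, c = NA_real_, r2 = NA_real_,
               bins_used = NA_integer_, fit_ok = FALSE)
      } else {
        tibble(m = fit$m, c = fit$c, r2 = fit$r2,
               bins_used = fit$bins_used, fit_ok = fit$r2 >= r2_min)
      }
    }) |>
    dplyr::ungroup()
}
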