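#' Configuration for the Monte Carlo huddling model
#'
#' The Monte Carlo model is aspatial: its state is a partition of `n`
#' individuals into disjoint groups ("aggregons"), iterated by Gibbs-sampled
#' merge/split decisions.
#'
#' @param n Number of individuals (default 12).
#' @param t Number of iterations (default 5000).
#' @param thermo A [thermo_params()] object.
#' @param burn_in Iterations discarded before computing metrics (default 0:
#'   metrics average over all iterations from the initial state).
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n = 12, t = 5000, thermo = thermo_params(t_a = 10),
                      burn_in = 0) {
  stopifnot(inherits(thermo, "thermo_params"))
  if (n < 2) abort("`n` must be at least 2.")
  if (t < 0 || burn_in < 0 || (burn_in >= t && !(t == 0 && burn_in == 0))) {
    abort("need `t` > `burn_in` >= 0.")
  }
  structure(list(n = n, t = t, thermo = thermo, burn_in = burn_in),
            class = "mc_config")
}

#' Probability that two colliding groups merge
#'
#' When individuals `a` and `b` from two different groups make contact, the
#' groups merge with probability
#' `p1 = 1 / (1 + exp((G_a n_a^(1/4) + G_b n_b^(1/4)) / k1 - 2 (T_P - T_A)))`,
#' the Gibbs acceptance probability for "temperature parameter"
#' `T = 2 T_P - T_B,a - T_B,b`: the colder the pair relative to the preferred
#' temperature, the more likely the merge. Otherwise `a` is displaced into a
#' singleton (probability `1 - p1`).
#'
#' @param g_a,g_b Metabolic rates of the two sampled individuals.
#' @param n_a,n_b Sizes of their current groups.
#' @param thermo A [thermo_params()] object.
#' @return Merge probability in `[0, 1]`; vectorised over the rates/sizes.
#' @examples
#' merge_probability(0, 1, 0, 1, thermo_params(t_a = 37))  # 0.5
#' @export
merge_probability <- function(g_a, n_a, g_b, n_b, thermo) {
  stopifnot(inherits(thermo, "thermo_params"))
  if (any(n_a < 1) || any(n_b < 1)) abort("group sizes must be >= 1.")
  expo <- (g_a * n_a^0.25 + g_b * n_b^0.25) / thermo$k1 -
    2 * (thermo$t_p - thermo$t_a)
  1 / (1 + exp(expo))
}

#' Sample a contact pair from two different groups
#'
#' Individual `a` is a uniformly chosen individual (so a group is selected
#' with probability proportional to its size, `n_i / N`); `b` is uniform over
#' the individuals outside `a`'s group (`n_j / (N - n_a)` per group).
#'
#' @param membership Integer vector of group labels, one per individual.
#' @return Integer vector `c(a, b)` of 1-based individual indices.
#' @export
sample_pair <- function(membership) {
  sample_pair_cpp(as.integer(membership))
}

#' One Gibbs merge/split iteration
#'
#' Special cases: from a single group a uniformly chosen individual is always
#' split off (`p1 = 0`); from all singletons the sampled pair always merges
#' (`p2 = 0`). Otherwise the sampled pair's groups merge with probability
#' [merge_probability()], else `a` becomes a singleton. Merged groups take a
#' fresh label; labels are bookkeeping only.
#'
#' @param membership Integer vector of group labels, one per individual.
#' @param g Metabolic rate per individual.
#' @param thermo A [thermo_params()] object.
#' @return The new membership vector.
#' @export
mc_step <- function(membership, g, thermo) {
  stopifnot(inherits(thermo, "thermo_params"), length(g) == length(membership))
  mc_step_cpp(as.integer(membership), as.numeric(g),
              thermo$t_a, thermo$t_p, thermo$k1)
}

#' Run the Monte Carlo huddling model
#'
#' Iterates [mc_step()] from an initial partition (default: a single group of
#' all `n` individuals) and records, after every iteration, each individual's
#' group size, exposed-area fraction `A_i = n_i^(-1/4)` and equilibrium body
#' temperature `T_B,i = T_A + G_i / (A_i k1)`.
#'
#' @param config An [mc_config()] object.
#' @param g Metabolic rate per individual (length `config$n`).
#' @param initial Optional initial membership vector; default one group.
#' @return A tibble of class `mc_trajectory` with columns `iteration`,
#'   `individual`, `group_size`, `a`, `t_b` and the per-iteration huddling
#'   metric `h = 1 - mean(A_i)`.
#' @examples
#' cfg <- mc_config(t = 200, thermo = thermo_params(t_a = 10))
#' set.seed(1)
#' traj <- run_mc(cfg, g = runif(12, 0, 5))
#' mc_metrics(traj)
#' @export
run_mc <- function(config, g, initial = rep(1L, config$n)) {
  stopifnot(inherits(config, "mc_config"), length(g) == config$n,
            length(initial) == config$n)
  th <- config$thermo
  sizes <- run_mc_cpp(as.integer(initial), as.numeric(g),
                      th$t_a, th$t_p, th$k1, config$t)
  t_len <- nrow(sizes)
  traj <- tibble(
    iteration = rep(seq_len(t_len), times = config$n),
    individual = rep(seq_len(config$n), each = t_len),
    group_size = as.integer(sizes),
    g = rep(as.numeric(g), each = t_len)
  )
  traj$a <- traj$group_size^(-0.25)
  traj$t_b <- th$t_a + traj$g / (traj$a * th$k1)
  traj <- traj |>
    dplyr::group_by(.data$iteration) |>
    dplyr::mutate(h = 1 - mean(.data$a)) |>
    dplyr::ungroup()
  attr(traj, "config") <- config
  class(traj) <- c("mc_trajectory", class(traj))
  traj
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarise a Monte Carlo trajectory
#'
#' @param traj An `mc_trajectory` from [run_mc()].
#' @param burn_in Iterations discarded from the start (default: the
#'   trajectory config's `burn_in`).
#' @return A one-row tibble with `h_mean` (mean huddling), `pup_flow`
#'   (population standard deviation of `h` over iterations), `groups_mean`
#'   (mean number of groups) and `t_b_mean` (grand mean body temperature),
#'   plus a list-column `t_b_individual` of per-individual time averages
#'   (these feed the fitness function).
#' @export
mc_metrics <- function(traj, burn_in = NULL) {
  cfg <- attr(traj, "config")
  if (is.null(burn_in)) burn_in <- if (is.null(cfg)) 0 else cfg$burn_in
  kept <- dplyr::filter(traj, .data$iteration > burn_in)
  if (nrow(kept) == 0) abort("no iterations retained after burn-in.")
  per_iter <- kept |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(
      h = .data$h[1],
      # each group of size s contributes s individuals reporting size s,
      # so the group count is sum over individuals of 1/n_i
      n_groups = sum(1 / .data$group_size),
      .groups = "drop"
    )
  t_b_ind <- kept |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(t_b_mean = mean(.data$t_b), .groups = "drop")
  tibble(
    h_mean = mean(per_iter$h),
    pup_flow = pop_sd(per_iter$h),
    groups_mean = mean(per_iter$n_groups),
    t_b_mean = mean(kept$t_b),
    t_b_individual = list(t_b_ind$t_b_mean)
  )
}

#' Sweep the Monte Carlo model over ambient temperatures
#'
#' One independent simulation per ambient temperature; metabolic rates are
#' redrawn `G ~ U(g_range)` for each simulation.
#'
#' @param config An [mc_config()] template; its `t_a` is overridden per row.
#' @param t_a_values Ambient temperatures to simulate (degrees C).
#' @param g_range Range for the uniform metabolic-rate draw.
#' @param replicates Independent simulations per temperature (default 1).
#' @return A tibble with one row per temperature and replicate:
#'   `t_a`, `replicate`, `h_mean`, `pup_flow`, `groups_mean`, `t_b_mean`.
#' @export
mc_temperature_sweep <- function(config, t_a_values = seq(0, 50, by = 2),
                                 g_range = c(0, 5), replicates = 1) {
  if (length(t_a_values) == 0) abort("`t_a_values` must be non-empty.")
  grid <- tidyr::expand_grid(t_a = t_a_values, replicate = seq_len(replicates))
  purrr::pmap_dfr(grid, function(t_a, replicate) {
    th <- config$thermo
    th$t_a <- t_a
    g <- runif(config$n, g_range[1], g_range[2])
    res <- run_mc_summary_cpp(rep(1L, config$n), g, th$t_a, th$t_p, th$k1,
                              config$t)
    tibble(
      t_a = t_a, replicate = replicate,
      h_mean = res$h_mean, pup_flow = res$pup_flow,
      groups_mean = res$groups_mean, t_b_mean = mean(res$mean_tb)
    )
  })
}
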