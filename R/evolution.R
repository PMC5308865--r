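#' Configuration for weakest-substitution evolution
#'
#' Each generation, the configured simulator is run afresh for
#' `per_gen_iterations` steps, every individual's fitness is computed from its
#' time-averaged body temperature, and the single least-fit individual is
#' replaced by one with a physiology drawn uniformly at random. Exactly one
#' physiology changes per generation, so any long-range structure in the
#' evolutionary dynamics must be carried by the huddling interactions.
#'
#' @param model `"monte_carlo"` or `"agent_based"`.
#' @param generations Number of generations (default 10000).
#' @param per_gen_iterations Simulator iterations/timesteps per generation
#'   (default 1000).
#' @param thermo A [thermo_params()] object. Defaults: `alpha = 6.06` for the
#'   Monte Carlo model (`k1 = 0.3`), `alpha = 3` for the agent-based model
#'   (`k1 = 1`).
#' @param n Population size (default 12).
#' @param g_range Uniform range for substituted metabolic rates (default
#'   `c(0, 5)`).
#' @param k2_range Uniform range for substituted contact conductances
#'   (agent-based model only; default `c(0, 5)`).
#' @param abm Optional [abm_config()] overriding the agent-based simulator
#'   settings (its `t`, `thermo` and `n` are taken from this config).
#' @return A list of class `evolution_config`.
#' @export
evolution_config <- function(model = c("monte_carlo", "agent_based"),
                             generations = 10000, per_gen_iterations = 1000,
                             thermo = NULL, n = 12, g_range = c(0, 5),
                             k2_range = c(0, 5), abm = NULL) {
  model <- match.arg(model)
  if (is.null(thermo)) {
    thermo <- if (model == "monte_carlo") {
      thermo_params(t_a = 10, k1 = 0.3, alpha = 6.06)
    } else {
      thermo_params(t_a = 10, k1 = 1, alpha = 3)
    }
  }
  stopifnot(inherits(thermo, "thermo_params"))
  if (generations < 1) abort("`generations` must be >= 1.")
  if (diff(g_range) <= 0 || diff(k2_range) <= 0) {
    abort("physiology ranges must be non-degenerate.")
  }
  if (is.null(abm) && model == "agent_based") abm <- abm_config()
  if (!is.null(abm)) {
    abm$t <- per_gen_iterations
    abm$thermo <- thermo
    abm$n <- n
  }
  structure(list(model = model, generations = generations,
                 per_gen_iterations = per_gen_iterations, thermo = thermo,
                 n = n, g_range = g_range, k2_range = k2_range, abm = abm),
            class = "evolution_config")
}

#' Evaluate one generation
#'
#' Runs the configured simulator from a fresh initial state (a single group
#' for the Monte Carlo model; random placement for the agent-based model),
#' averages each individual's body temperature over all iterations, and
#' scores fitness `F = -(|T_B_mean - T_P| + alpha G)`. The weakest individual
#' is the lowest index attaining the minimum fitness; `g_min` is the largest
#' metabolic rate among the others (the would-be second-weakest).
#'
#' @param physiologies A tibble with columns `g` and `k2`.
#' @param config An [evolution_config()] object.
#' @return A one-row tibble with list-columns `f`, `t_b_mean` and scalars
#'   `weakest`, `g_weakest`, `g_min`, `f_weakest`, `f_mean`.
#' @export
evaluate_generation <- function(physiologies, config) {
  stopifnot(inherits(config, "evolution_config"),
            nrow(physiologies) == config$n)
  th <- config$thermo
  if (config$model == "monte_carlo") {
    sim <- run_mc_summary_cpp(rep(1L, config$n), physiologies$g,
                              th$t_a, th$t_p, th$k1,
                              config$per_gen_iterations)
    t_b <- sim$mean_tb
  } else {
    out <- run_abm(config$abm, physiologies, record = FALSE)
    t_b <- out$t_b_individual[[1]]
  }
  f <- huddling_fitness(t_b, physiologies$g, th)
  weakest <- which.min(f) # lowest index among ties
  tibble(
    weakest = weakest,
    g_weakest = physiologies$g[weakest],
    g_min = max(physiologies$g[-weakest]),
    f_weakest = f[weakest],
    f_mean = mean(f),
    f = list(f),
    t_b_mean = list(t_b)
  )
}

#' Replace the weakest individual's physiology
#'
#' @param physiologies A tibble with columns `g` and `k2`.
#' @param weakest Index of the individual to replace.
#' @param config An [evolution_config()] object.
#' @return The physiologies with row `weakest` redrawn uniformly (both `g`
#'   and `k2` for the agent-based model; `k2` is redrawn but inert for the
#'   Monte Carlo model) and every other row untouched.
#' @export
substitute_weakest <- function(physiologies, weakest, config) {
  stopifnot(inherits(config, "evolution_config"),
            weakest >= 1, weakest <= nrow(physiologies))
  physiologies$g[weakest] <- runif(1, config$g_range[1], config$g_range[2])
  physiologies$k2[weakest] <- runif(1, config$k2_range[1], config$k2_range[2])
  physiologies
}

#' Evolve a huddling population by weakest substitution
#'
#' Initial physiologies are drawn uniformly from the configured ranges; then
#' for each generation [evaluate_generation()] is followed by
#' [substitute_weakest()].
#'
#' @param config An [evolution_config()] object.
#' @param seed Optional integer seed; when supplied the run is reproducible.
#' @param progress Print a dot every 1000 generations.
#' @return A tibble of class `evolution_trace` with one row per generation:
#'   `generation`, `weakest`, `g_weakest` (the substituted individual's
#'   metabolic rate), `g_min` (largest G of the remainder), `f_weakest`,
#'   `f_mean`, and
#'   list-columns `f`, `g`, `k2` of the full per-individual values at
#'   evaluation time.
#' @examples
#' cfg <- evolution_config("monte_carlo", generations = 20,
#'                         per_gen_iterations = 100)
#' tr <- evolve(cfg, seed = 1)
#' @export
evolve <- function(config, seed = NULL, progress = FALSE) {
  stopifnot(inherits(config, "evolution_config"))
  run <- function() {
    phys <- draw_physiologies(config$n, config$g_range, config$k2_range)
    gens <- config$generations
    weakest <- integer(gens)
    g_weakest <- g_min <- f_weakest <- f_mean <- numeric(gens)
    f_l <- g_l <- k2_l <- vector("list", gens)
    for (gen in seq_len(gens)) {
      rec <- evaluate_generation(phys, config)
      weakest[gen] <- rec$weakest
      g_weakest[gen] <- rec$g_weakest
      g_min[gen] <- rec$g_min
      f_weakest[gen] <- rec$f_weakest
      f_mean[gen] <- rec$f_mean
      f_l[[gen]] <- rec$f[[1]]
      g_l[[gen]] <- phys$g
      k2_l[[gen]] <- phys$k2
      phys <- substitute_weakest(phys, rec$weakest, config)
      if (progress && gen %% 1000 == 0) cat(".")
    }
    if (progress) cat("\n")
    out <- tibble(
      generation = seq_len(gens), weakest = weakest, g_weakest = g_weakest,
      g_min = g_min, f_weakest = f_weakest, f_mean = f_mean,
      f = f_l, g = g_l, k2 = k2_l
    )
    attr(out, "config") <- config
    class(out) <- c("evolution_trace", class(out))
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
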