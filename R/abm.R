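#' Configuration for the agent-based huddling model
#'
#' Agents are circles of radius `agent_radius` moving inside a circular arena.
#' Each carries `n_sensors` thermal sensors around its circumference; sensor
#' temperatures drive homeothermotaxis turning and contact heat exchange.
#'
#' @param n Number of agents (default 12).
#' @param t Timesteps per simulation (default 1000).
#' @param dt Integration timestep (default 0.05).
#' @param agent_radius Agent radius; the model's length unit (default 1).
#' @param arena_radius Arena radius (default 6.5, giving an area packing
#'   fraction of about 0.28 for 12 agents: dense enough for frequent contact,
#'   sparse enough for dispersal above the preferred temperature).
#' @param v1 Forward speed (length per time, default 1).
#' @param v2 Turning-rate gain (default 5).
#' @param sigma Sensor gain (per degree squared, default 0.01): keeps the
#'   logistic argument of order one for temperature products of order 100.
#' @param n_sensors Circumferential sensors (default 72; must be >= 8).
#' @param contact_slack Relative tolerance on centre distance for the contact
#'   graph used in group labelling (default 0.05).
#' @param overlap_tol Maximum residual body overlap, in length units
#'   (default 0.5, half an agent radius). Overlap resolution restores pairs
#'   only to a centre distance of `2 agent_radius - overlap_tol`: pups are
#'   soft-bodied, and the tolerated compression is what gives contacting
#'   agents a finite contact arc for their sensors to register.
#' @param n_resolve Overlap-resolution sweeps per step (default 5).
#' @param thermo A [thermo_params()] object; `k1` is the conductance to the
#'   environment (the evolution experiments fix it at 1) and `alpha` defaults
#'   to 3.
#' @param burn_in Timesteps discarded before computing metrics (default 0).
#' @return A list of class `abm_config`.
#' @export
abm_config <- function(n = 12, t = 1000, dt = 0.05, agent_radius = 1,
                       arena_radius = 6.5, v1 = 1, v2 = 5, sigma = 0.01,
                       n_sensors = 72, contact_slack = 0.05,
                       overlap_tol = 0.5, n_resolve = 5,
                       thermo = thermo_params(t_a = 10, k1 = 1, alpha = 3),
                       burn_in = 0) {
  stopifnot(inherits(thermo, "thermo_params"))
  if (dt <= 0 || v1 <= 0 || v2 <= 0) abort("`dt`, `v1`, `v2` must be positive.")
  if (n_sensors < 8) abort("`n_sensors` must be at least 8.")
  if (arena_radius <= agent_radius) abort("arena cannot contain an agent.")
  if (overlap_tol < 0 || overlap_tol >= agent_radius) {
    abort("`overlap_tol` must be in [0, agent_radius).")
  }
  if (n * agent_radius^2 > 0.9 * (arena_radius - agent_radius)^2) {
    abort("arena cannot contain all agents without overlap.")
  }
  structure(list(n = n, t = t, dt = dt, agent_radius = agent_radius,
                 arena_radius = arena_radius, v1 = v1, v2 = v2, sigma = sigma,
                 n_sensors = n_sensors, contact_slack = contact_slack,
                 overlap_tol = overlap_tol, n_resolve = n_resolve,
                 thermo = thermo, burn_in = burn_in),
            class = "abm_config")
}

#' Thermal sensor reading for one agent
#'
#' Each of `n_sensors` points on the agent's circumference registers the body
#' temperature of the nearest other agent whose body strictly contains the
#' sensor point, or else the ambient temperature. Sensors left/right of the
#' heading are averaged to `t_l`/`t_r` (on-axis sensors are assigned
#' alternately); `a` is the fraction registering ambient (the exposed-area
#' fraction) and `t_c` the mean over contacting sensors (`NA` when `a = 1`).
#' The logistic sensor values `s_l`, `s_r` incorporate the gap between body
#' and preferred temperature (see [sensor_map()]).
#'
#' @param agents A data frame with columns `x`, `y`, `theta`, `t_b`, one row
#'   per agent.
#' @param i Index of the sensing agent.
#' @param config An [abm_config()] object.
#' @return A one-row tibble with columns `t_l`, `t_r`, `a`, `t_c`, `s_l`, `s_r`.
#' @export
sense <- function(agents, i, config) {
  stopifnot(inherits(config, "abm_config"),
            all(c("x", "y", "theta", "t_b") %in% names(agents)))
  th <- config$thermo
  r <- sense_cpp(agents$x, agents$y, agents$theta, agents$t_b, as.integer(i),
                 th$t_a, th$t_p, config$sigma, config$n_sensors,
                 config$agent_radius)
  as_tibble(r)
}

#' Logistic sensor map
#'
#' `s = 1 / (1 + exp(-sigma (T_P - T_B) T_side))`: equals 0.5 when the body is
#' at the preferred temperature (or the sensed temperature is zero) and rises
#' above 0.5 toward warm sensors when the agent is colder than it prefers
#' (the reverse when overheated), which is what makes turning reduce
#' `|T_B - T_P|`.
#'
#' @param t_side Sensed side temperature (degrees C).
#' @param t_b Agent body temperature (degrees C).
#' @param config An [abm_config()] object (supplies `sigma` and `t_p`).
#' @return Sensor value(s) in (0, 1).
#' @export
sensor_map <- function(t_side, t_b, config) {
  stopifnot(inherits(config, "abm_config"))
  1 / (1 + exp(-config$sigma * (config$thermo$t_p - t_b) * t_side))
}

#' Homeothermotaxis turning rate
#'
#' `d(theta)/dt = arctan(v2 (s_l - s_r) / (s_l + s_r))`: zero when the two
#' sides agree, bounded in (-pi/2, pi/2), and antisymmetric under a left/right
#' swap.
#'
#' @param s_l,s_r Left/right sensor values in (0, 1).
#' @param v2 Turning-rate gain.
#' @return Turning rate in radians per unit time.
#' @export
turn_rate <- function(s_l, s_r, v2) {
  if (any(s_l + s_r <= 0)) abort("`s_l + s_r` must be positive.")
  atan(v2 * (s_l - s_r) / (s_l + s_r))
}

#' Explicit-Euler body-temperature update
#'
#' Integrates `dT_B/dt = G - k1 A (T_B - T_A) - k2 (1 - A)(T_B - T_C)`:
#' thermogenesis, Newtonian loss through the exposed surface, and heat
#' exchange with contacting bodies. The contact term is dropped when `a = 1`
#' (its `1 - A` factor vanishes and `t_c` is undefined). For an isolated
#' agent the fixed point is the equilibrium `T_A + G / k1`.
#'
#' @param t_b Current body temperature.
#' @param g,k2 The agent's metabolic rate and contact conductance.
#' @param a Exposed-area fraction from [sense()].
#' @param t_c Mean contact temperature (ignored when `a = 1`).
#' @param config An [abm_config()] object.
#' @return The body temperature after one timestep.
#' @export
step_heat <- function(t_b, g, k2, a, t_c, config) {
  stopifnot(inherits(config, "abm_config"))
  th <- config$thermo
  d <- g - th$k1 * a * (t_b - th$t_a)
  contact <- a < 1
  d <- d - ifelse(contact, k2 * (1 - a) * (t_b - ifelse(contact, t_c, 0)), 0)
  t_b + config$dt * d
}

#' Label contact groups of agents
#'
#' Agents whose centre distance is below `2 agent_radius (1 + contact_slack)`
#' are in contact; groups are the connected components of the contact graph.
#'
#' @param agents A data frame with columns `x`, `y`.
#' @param config An [abm_config()] object.
#' @return The input with columns `group` (component label) and `group_size`.
#' @export
label_groups <- function(agents, config) {
  stopifnot(inherits(config, "abm_config"))
  n <- nrow(agents)
  thr <- 2 * config$agent_radius * (1 + config$contact_slack)
  d <- as.matrix(stats::dist(cbind(agents$x, agents$y)))
  adj <- d < thr
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  out <- as_tibble(agents)
  out$group <- as.integer(comp$membership)
  out$group_size <- as.integer(comp$csize[comp$membership])
  out
}

#' Place agents at random non-overlapping positions
#'
#' Rejection sampling of centres uniform in the admissible disk; headings
#' uniform on the circle; body temperatures start at the preferred
#' temperature.
#'
#' @param config An [abm_config()] object.
#' @param max_tries Placement attempts before giving up.
#' @return A tibble with columns `x`, `y`, `theta`, `t_b`.
#' @export
init_agents <- function(config, max_tries = 10000) {
  n <- config$n
  rmax <- config$arena_radius - config$agent_radius
  xs <- ys <- numeric(0)
  tries <- 0
  while (length(xs) < n) {
    if ((tries <- tries + 1) > max_tries) {
      abort("could not place all agents without overlap.")
    }
    rr <- rmax * sqrt(runif(1))
    ang <- runif(1, 0, 2 * pi)
    x <- rr * cos(ang); y <- rr * sin(ang)
    if (length(xs) == 0 ||
        all((xs - x)^2 + (ys - y)^2 >= (2 * config$agent_radius)^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  tibble(x = xs, y = ys, theta = runif(n, 0, 2 * pi),
         t_b = rep(config$thermo$t_p, n))
}

#' Run the agent-based huddling model
#'
#' From random non-overlapping positions, each timestep senses all agents,
#' turns and moves them (Euler integration of the self-propulsion and
#' homeothermotaxis equations), resolves overlaps and wall crossings, and
#' updates body temperatures by contact heat exchange.
#'
#' @param config An [abm_config()] object.
#' @param physiologies A data frame with columns `g` and `k2`, one row per
#'   agent (see [draw_physiologies()]).
#' @param initial Optional initial agent state from [init_agents()].
#' @param record If `FALSE`, skip the per-step trajectory and return summary
#'   metrics only (used by the evolutionary loop).
#' @return If `record`, a tibble of class `abm_trajectory` with columns
#'   `step`, `agent`, `x`, `y`, `a`, `t_b`, `n_groups`; otherwise a one-row
#'   summary tibble like [abm_metrics()] with a `t_b_individual` list-column.
#' @examples
#' cfg <- abm_config(t = 50)
#' set.seed(1)
#' traj <- run_abm(cfg, draw_physiologies(12))
#' abm_metrics(traj)
#' @export
run_abm <- function(config, physiologies, initial = NULL, record = TRUE) {
  stopifnot(inherits(config, "abm_config"),
            all(c("g", "k2") %in% names(physiologies)),
            nrow(physiologies) == config$n)
  if (is.null(initial)) initial <- init_agents(config)
  th <- config$thermo
  res <- run_abm_cpp(initial$x, initial$y, initial$theta, initial$t_b,
                     physiologies$g, physiologies$k2, th$t_a, th$t_p, th$k1,
                     config$sigma, config$v1, config$v2, config$dt, config$t,
                     config$n_sensors, config$agent_radius,
                     config$arena_radius, config$contact_slack,
                     config$overlap_tol, config$n_resolve, record)
  if (!record) {
    return(tibble(
      huddling = res$huddling, pup_flow = res$pup_flow,
      groups_mean = res$groups_mean, t_b_mean = mean(res$mean_tb),
      t_b_individual = list(res$mean_tb)
    ))
  }
  t_len <- config$t
  traj <- tibble(
    step = rep(seq_len(t_len), times = config$n),
    agent = rep(seq_len(config$n), each = t_len),
    x = as.numeric(res$x), y = as.numeric(res$y),
    a = as.numeric(res$a), t_b = as.numeric(res$tb),
    n_groups = rep(as.integer(res$ngroups), times = config$n)
  )
  attr(traj, "config") <- config
  class(traj) <- c("abm_trajectory", class(traj))
  traj
}

#' Summarise an agent-based trajectory
#'
#' @param traj An `abm_trajectory` from [run_abm()].
#' @param burn_in Timesteps discarded from the start (default: the config's).
#' @return A one-row tibble: `huddling` (`1 - mean(A)`), `pup_flow` (time- and
#'   agent-averaged `|dA/dt|`), `groups_mean`, `t_b_mean`, and the
#'   `t_b_individual` list-column of per-agent time averages.
#' @export
abm_metrics <- function(traj, burn_in = NULL) {
  cfg <- attr(traj, "config")
  if (is.null(burn_in)) burn_in <- if (is.null(cfg)) 0 else cfg$burn_in
  dt <- if (is.null(cfg)) 1 else cfg$dt
  kept <- dplyr::filter(traj, .data$step > burn_in)
  if (nrow(kept) == 0) abort("no steps retained after burn-in.")
  flow <- kept |>
    dplyr::group_by(.data$agent) |>
    dplyr::summarise(
      flow = if (dplyr::n() > 1) mean(abs(diff(.data$a)) / dt) else 0,
      t_b_mean = mean(.data$t_b),
      .groups = "drop"
    )
  per_step <- kept |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(n_groups = .data$n_groups[1], .groups = "drop")
  tibble(
    huddling = 1 - mean(kept$a),
    pup_flow = mean(flow$flow),
    groups_mean = mean(per_step$n_groups),
    t_b_mean = mean(kept$t_b),
    t_b_individual = list(flow$t_b_mean)
  )
}

#' Sweep the agent-based model over ambient temperatures
#'
#' Independent replicate simulations at each ambient temperature, with
#' physiologies redrawn per simulation.
#'
#' @param config An [abm_config()] template; `t_a` is overridden per row.
#' @param t_a_values Ambient temperatures (degrees C).
#' @param replicates Simulations per temperature (default 20).
#' @param g_range,k2_range Uniform ranges for the redrawn physiologies.
#' @return A tibble with one row per temperature and replicate (`t_a`,
#'   `replicate`, `huddling`, `pup_flow`, `groups_mean`, `t_b_mean`,
#'   `g_mean`).
#' @export
abm_temperature_sweep <- function(config, t_a_values = seq(0, 50, by = 2),
                                  replicates = 20, g_range = c(0, 5),
                                  k2_range = c(0, 5)) {
  if (length(t_a_values) == 0) abort("`t_a_values` must be non-empty.")
  grid <- tidyr::expand_grid(t_a = t_a_values, replicate = seq_len(replicates))
  purrr::pmap_dfr(grid, function(t_a, replicate) {
    cfg <- config
    cfg$thermo$t_a <- t_a
    phys <- draw_physiologies(cfg$n, g_range, k2_range)
    out <- run_abm(cfg, phys, record = FALSE)
    dplyr::bind_cols(
      tibble(t_a = t_a, replicate = replicate),
      dplyr::select(out, -"t_b_individual"),
      tibble(g_mean = mean(phys$g))
    )
  })
}
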