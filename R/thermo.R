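#' Thermal environment and cost parameters
#'
#' Bundles the parameters shared by both huddling simulators: the ambient
#' temperature, the preferred body temperature, the area-specific wet thermal
#' conductance to the environment, and the weight of the thermogenesis cost in
#' the fitness function.
#'
#' @param t_a Ambient temperature in degrees C.
#' @param t_p Preferred body temperature in degrees C (default 37).
#' @param k1 Area-specific wet thermal conductance (heat per degree per unit
#'   exposed area; must be positive). This single rate constant lumps fur,
#'   emittance, air properties and body geometry.
#' @param alpha Non-negative weight of the thermogenesis cost term in the
#'   fitness function. The Monte Carlo evolution experiments use 6.06, the
#'   agent-based ones 3.0.
#'
#' @return A list of class `thermo_params`.
#' @examples
#' thermo_params(t_a = 10, k1 = 0.3)
#' @export
thermo_params <- function(t_a, t_p = 37, k1 = 0.3, alpha = 6.06) {
  stopifnot(is.numeric(t_a), length(t_a) == 1L, is.finite(t_a))
  if (!is.numeric(k1) || length(k1) != 1L || !is.finite(k1) || k1 <= 0) {
    abort("`k1` must be a single positive number.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0) {
    abort("`alpha` must be a single non-negative number.")
  }
  structure(list(t_a = t_a, t_p = t_p, k1 = k1, alpha = alpha),
            class = "thermo_params")
}

#' Exposed surface-area fraction of an individual in a group of size n
#'
#' The average fraction of its surface that an individual in a group of `n`
#' bodies keeps exposed to the environment decays as a power of the group
#' size: `A = n^(-1/4)`. A singleton is fully exposed (`A = 1`).
#'
#' @param n Group size(s); positive integer-valued.
#' @return Numeric vector of exposed-area fractions in (0, 1].
#' @examples
#' exposed_area(1)   # 1
#' exposed_area(16)  # 0.5
#' @export
exposed_area <- function(n) {
  if (!is.numeric(n) || length(n) == 0L || anyNA(n) ||
      any(n < 1) || any(n != round(n))) {
    abort("`n` must be positive integer-valued group size(s).")
  }
  n^(-0.25)
}

#' Equilibrium body temperature under Newtonian heat balance
#'
#' Steady state of heat production `G` against conductive loss through the
#' exposed fraction `A` of the body surface:
#' `T_B = T_A + G / (A * k1)`.
#'
#' @param t_a Ambient temperature (degrees C).
#' @param g Metabolic heat-production rate (non-negative).
#' @param a Exposed-area fraction in (0, 1].
#' @param k1 Thermal conductance to the environment (positive).
#' @return Body temperature(s) in degrees C; always `>= t_a`.
#' @examples
#' equilibrium_body_temperature(10, g = 3, a = 1, k1 = 0.3)    # 20
#' equilibrium_body_temperature(10, g = 3, a = 0.5, k1 = 0.3)  # 30
#' @export
equilibrium_body_temperature <- function(t_a, g, a, k1) {
  if (any(a <= 0)) abort("`a` must be positive: a fully enclosed body has no equilibrium.")
  if (any(k1 <= 0)) abort("`k1` must be positive.")
  if (any(g < 0)) abort("`g` must be non-negative.")
  t_a + g / (a * k1)
}

#' Fitness of an individual thermal physiology
#'
#' An individual is fitter the closer its time-averaged body temperature stays
#' to the preferred temperature and the less heat it produces:
#' `F = -(|T_B_mean - T_P| + alpha * G)`. The maximum, 0, is attained only by
#' perfect thermoregulation at zero metabolic cost.
#'
#' @param t_b_mean Time-averaged body temperature (degrees C); vectorised.
#' @param g Metabolic heat-production rate(s).
#' @param params A [thermo_params()] object supplying `t_p` and `alpha`.
#' @return Fitness value(s), always `<= 0`.
#' @examples
#' huddling_fitness(10, g = 0, thermo_params(t_a = 10))  # -27
#' @export
huddling_fitness <- function(t_b_mean, g, params) {
  stopifnot(inherits(params, "thermo_params"))
  -(abs(t_b_mean - params$t_p) + params$alpha * g)
}

#' Draw a population of thermal physiologies
#'
#' Metabolic rates (and, for the agent-based model, body-to-body contact
#' conductances) are drawn independently and uniformly from the configured
#' ranges.
#'
#' @param n Population size.
#' @param g_range Length-2 range for the metabolic rate G.
#' @param k2_range Length-2 range for the contact conductance k2.
#' @return A tibble with columns `g` and `k2`, one row per individual.
#' @export
draw_physiologies <- function(n, g_range = c(0, 5), k2_range = c(0, 5)) {
  stopifnot(n >= 1, length(g_range) == 2L, length(k2_range) == 2L)
  tibble(
    g  = runif(n, g_range[1], g_range[2]),
    k2 = runif(n, k2_range[1], k2_range[2])
  )
}
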