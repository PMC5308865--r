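test_that("sensor map and turn rate follow their closed forms", {
  cfg <- fast_abm_cfg()
  expect_equal(sensor_map(20, t_b = 37, cfg), 0.5)
  expect_equal(sensor_map(0, t_b = 20, cfg), 0.5)
  # sigma = 0.01, T_P - T_B = 10, T_side = 20 -> logistic(2)
  expect_equal(sensor_map(20, t_b = 27, cfg), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  # warm side looks good to a cold agent, bad to a hot one
  expect_gt(sensor_map(30, t_b = 20, cfg), 0.5)
  expect_lt(sensor_map(30, t_b = 45, cfg), 0.5)

  expect_equal(turn_rate(0.4, 0.4, v2 = 5), 0)
  expect_equal(turn_rate(0.9, 0.1, v2 = 1), atan(0.8))
  expect_equal(turn_rate(0.1, 0.9, v2 = 1), -atan(0.8))
  expect_true(all(abs(turn_rate(runif(50), runif(50) + 1e-6, 5)) < pi / 2))
  expect_error(turn_rate(0, 0, 5))
})

test_that("circumferential sensing reports contacts, exposure and sides", {
  cfg <- fast_abm_cfg(t_a = 15)
  # isolated agent: fully exposed, both sides read ambient
  lone <- tibble::tibble(x = 0, y = 0, theta = 0, t_b = 20)
  r <- sense(lone, 1, cfg)
  expect_equal(r$a, 1)
  expect_equal(r$t_l, 15)
  expect_equal(r$t_r, 15)
  expect_true(is.na(r$t_c))
  expect_equal(r$s_l, r$s_r)

  # agent ringed by six warm bodies at distance 1.2: fully enclosed
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- tibble::tibble(
    x = c(0, 1.2 * cos(ang)), y = c(0, 1.2 * sin(ang)),
    theta = 0, t_b = c(20, rep(33, 6))
  )
  r <- sense(ring, 1, cfg)
  expect_equal(r$a, 0)
  expect_equal(r$t_c, 33)

  # a single warm contact on the left beam: warm left, exposed elsewhere
  pair <- tibble::tibble(x = c(0, 0), y = c(0, 1.6), theta = c(0, 0),
                         t_b = c(20, 35))
  r <- sense(pair, 1, cfg)
  expect_lt(r$a, 1)
  expect_gt(r$a, 0.5)
  expect_gt(r$t_l, r$t_r)
  expect_equal(r$t_r, 15) # right side all ambient
  expect_gt(r$s_l, r$s_r) # cold agent steers toward the warmth
})

test_that("heat update has the isolated fixed point and Newtonian decay", {
  cfg <- fast_abm_cfg(t_a = 10)
  # at T_B = T_A + G/k1 with full exposure, temperature is stationary
  expect_equal(step_heat(13, g = 3, k2 = 2, a = 1, t_c = NA, cfg), 13)
  # pure cooling when G = 0 and exposed
  expect_lt(step_heat(30, g = 0, k2 = 2, a = 1, t_c = NA, cfg), 30)
  # fully enclosed with G = 0: exponential relaxation to the contact
  # temperature at rate k2 (compare Euler to the closed form over 2000
  # small steps)
  cfg_fine <- fast_abm_cfg(t_a = 10, dt = 0.001)
  tb <- 20
  for (i in 1:2000) tb <- step_heat(tb, g = 0, k2 = 1.5, a = 0, t_c = 30,
                                    cfg_fine)
  expect_equal(tb, 30 + (20 - 30) * exp(-1.5 * 2), tolerance = 1e-2)
})

test_that("Euler integration matches the closed-form isolated solution, first order", {
  # an isolated agent cooling/warming toward T_A + G/k1 from T_P
  closed <- function(t, t0, ta, g, k1) ta + g / k1 + (t0 - ta - g / k1) * exp(-k1 * t)
  err_for <- function(dt) {
    cfg <- abm_config(n = 1, t = round(10 / dt), dt = dt,
                      thermo = thermo_params(t_a = 10, k1 = 1, alpha = 3))
    withr::with_seed(8, {
      traj <- run_abm(cfg, tibble::tibble(g = 3, k2 = 1))
    })
    tb <- traj$t_b
    times <- traj$step * dt
    max(abs(tb - closed(times, 37, 10, 3, 1)))
  }
  e1 <- err_for(0.05)
  e2 <- err_for(0.025)
  expect_lt(e1 / (37 - 13), 0.01) # within 1% of the full excursion
  expect_lt(e2 / e1, 0.65)        # halving dt roughly halves the error
  expect_gt(e2 / e1, 0.35)
})

test_that("group labelling equals a breadth-first-search oracle", {
  cfg <- fast_abm_cfg()
  withr::with_seed(21, {
    for (i in 1:100) {
      n <- sample(2:12, 1)
      ag <- tibble::tibble(x = runif(n, -5, 5), y = runif(n, -5, 5))
      lab <- label_groups(ag, cfg)$group
      oracle <- bfs_components(ag$x, ag$y, cfg$agent_radius,
                               cfg$contact_slack)
      # same partition up to label permutation
      expect_equal(as.vector(table(lab)[as.character(lab)]),
                   as.vector(table(oracle)[as.character(oracle)]))
      expect_true(all((outer(lab, lab, "==")) == (outer(oracle, oracle, "=="))))
    }
  })
  # chain transitivity: a-b and b-c in contact, a-c distant -> one group
  chain <- tibble::tibble(x = c(0, 2, 4), y = 0)
  expect_equal(label_groups(chain, cfg)$group_size, c(3L, 3L, 3L))
  # all distant -> singletons
  far <- tibble::tibble(x = c(0, 5, -5), y = c(0, 5, -5))
  expect_equal(label_groups(far, cfg)$group, 1:3)
})

test_that("agents stay inside the arena with bounded overlaps", {
  cfg <- fast_abm_cfg(t_a = 5, t = 300)
  withr::with_seed(31, {
    traj <- run_abm(cfg, draw_physiologies(12))
  })
  rr <- sqrt(traj$x^2 + traj$y^2)
  expect_true(all(rr <= cfg$arena_radius - cfg$agent_radius + 1e-9))
  # pairwise distances never fall below the compression floor
  by_step <- split(traj, traj$step)
  min_d <- min(vapply(by_step, function(d) {
    min(stats::dist(cbind(d$x, d$y)))
  }, numeric(1)))
  expect_gte(min_d, 2 * cfg$agent_radius - cfg$overlap_tol - 0.15)
  # body temperatures remain bounded given bounded G and conductances
  expect_true(all(is.finite(traj$t_b)))
  expect_true(all(traj$t_b > -50 & traj$t_b < 150))
})

test_that("trajectory bookkeeping and metrics behave on edge cases", {
  cfg <- fast_abm_cfg(t = 0)
  withr::with_seed(4, traj <- run_abm(cfg, draw_physiologies(12)))
  expect_equal(nrow(traj), 0)

  # static configuration: isolated agents give huddling 0 and pup flow 0
  # (constructed by zero speed: agents cannot move)
  cfg2 <- abm_config(n = 3, t = 40, v1 = 1e-12, arena_radius = 20,
                     thermo = thermo_params(t_a = 10, k1 = 1, alpha = 3))
  withr::with_seed(5, {
    init <- tibble::tibble(x = c(0, 8, -8), y = c(0, 8, -8),
                           theta = 0, t_b = 37)
    traj2 <- run_abm(cfg2, draw_physiologies(3), initial = init)
  })
  m <- abm_metrics(traj2)
  expect_equal(m$huddling, 0)
  expect_equal(m$pup_flow, 0)
  expect_equal(m$groups_mean, 3)
  expect_error(abm_metrics(traj2, burn_in = 40), "burn-in")

  # record = FALSE returns the same summary as metrics on the recording
  cfg3 <- fast_abm_cfg(t = 60)
  withr::with_seed(6, {
    init <- init_agents(cfg3)
    phys <- draw_physiologies(12)
    full <- abm_metrics(run_abm(cfg3, phys, initial = init))
  })
  withr::with_seed(6, {
    init <- init_agents(cfg3)
    phys <- draw_physiologies(12)
    summ <- run_abm(cfg3, phys, initial = init, record = FALSE)
  })
  expect_equal(summ$huddling, full$huddling, tolerance = 1e-10)
  expect_equal(summ$t_b_individual[[1]], full$t_b_individual[[1]],
               tolerance = 1e-10)
})

test_that("initial placement is non-overlapping and inside the arena", {
  cfg <- fast_abm_cfg()
  withr::with_seed(12, ag <- init_agents(cfg))
  expect_equal(nrow(ag), 12)
  expect_true(all(sqrt(ag$x^2 + ag$y^2) <= cfg$arena_radius - 1))
  expect_gte(min(stats::dist(cbind(ag$x, ag$y))), 2)
  # a cramped arena is rejected at configuration time
  expect_error(abm_config(n = 12, arena_radius = 4.2), "arena")
  # and exhausted placement attempts error out
  withr::with_seed(13, expect_error(init_agents(cfg, max_tries = 5),
                                    "place"))
})

test_that("cold agents huddle more than hot agents and stay warmer than alone", {
  withr::with_seed(14, {
    cold <- abm_temperature_sweep(fast_abm_cfg(t = 600), 0, replicates = 3)
    hot <- abm_temperature_sweep(fast_abm_cfg(t = 600), 45, replicates = 3)
  })
  expect_gt(mean(cold$huddling), mean(hot$huddling))
  expect_lt(mean(hot$huddling), 0.15)
  # above-baseline warming from contact heat exchange
  expect_gt(mean(cold$t_b_mean), mean(0 + cold$g_mean / 1))
})
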