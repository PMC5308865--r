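test_that("merge probability matches its closed form and limits", {
  th0 <- thermo_params(t_a = 37, k1 = 0.3)
  expect_equal(merge_probability(0, 1, 0, 1, th0), 0.5)
  th_cold <- thermo_params(t_a = 0, k1 = 0.3)
  expect_equal(merge_probability(0, 1, 0, 1, th_cold), 1 / (1 + exp(-74)))
  th <- thermo_params(t_a = 27, k1 = 0.3)
  # exponent (1.5 + 1.5)/0.3 - 2*10 = -10
  expect_equal(merge_probability(1.5, 1, 1.5, 1, th), 1 / (1 + exp(-10)),
               tolerance = 1e-12)
  # equivalently the sigmoid of 2*T_P - T_B,a - T_B,b
  g <- c(1.2, 0.4); n <- c(3L, 2L)
  tb <- equilibrium_body_temperature(th$t_a, g, exposed_area(n), th$k1)
  expect_equal(merge_probability(g[1], n[1], g[2], n[2], th),
               1 / (1 + exp(-(2 * th$t_p - tb[1] - tb[2]))),
               tolerance = 1e-12)
  # warmer pairs are less likely to merge
  p <- merge_probability(seq(0, 5, 0.5), 2, 1, 2, th)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("pair sampling matches exhaustive enumeration for small litters", {
  # groups labelled by position: sizes c(3, 2, 1), N = 6
  sizes <- c(3L, 2L, 1L)
  m <- membership_of_sizes(sizes)
  p_oracle <- enumerate_pair_probs(sizes)
  withr::with_seed(42, {
    n_draw <- 20000
    counts <- matrix(0, 3, 3)
    for (i in seq_len(n_draw)) {
      ab <- sample_pair(m)
      counts[m[ab[1]], m[ab[2]]] <- counts[m[ab[1]], m[ab[2]]] + 1
    }
  })
  emp <- counts / sum(counts)
  # binomial error: 4 sd of each cell proportion
  tol <- 4 * sqrt(p_oracle * (1 - p_oracle) / 20000)
  expect_true(all(abs(emp - p_oracle) <= tol + 1e-12))
  # a and b always come from different groups
  expect_true(all(diag(counts) == 0))
})

test_that("pair sampling handles forced and degenerate cases", {
  expect_error(sample_pair(c(1L, 1L, 1L)), "two groups")
  # N = 2 singletons: the pair is forced
  ab <- sample_pair(c(1L, 2L))
  expect_setequal(ab, c(1L, 2L))
  # partition {11, 1}: P(a in the big group) = 11/12
  m <- membership_of_sizes(c(11L, 1L))
  withr::with_seed(7, {
    hits <- sum(replicate(5000, sample_pair(m)[1] <= 11))
  })
  expect_equal(hits / 5000, 11 / 12, tolerance = 0.02)
})

test_that("one Gibbs step preserves the partition and honours special cases", {
  th <- thermo_params(t_a = 10, k1 = 0.3)
  g12 <- rep(1, 12)
  # from a single group, always split into {N-1, 1}
  for (i in 1:20) {
    out <- mc_step(rep(1L, 12), g12, th)
    expect_equal(sizes_of_membership(out), c(11L, 1L))
  }
  # from all singletons, always merge into one pair
  for (i in 1:20) {
    out <- mc_step(1:12, g12, th)
    expect_equal(sizes_of_membership(out), c(2L, rep(1L, 10)))
  }
  # merge bookkeeping: {4, 6, 2} with certain merge gives sizes {10, 2}
  # or a split; under T_A far below T_P and G = 0 the merge is certain
  m <- membership_of_sizes(c(4L, 6L, 2L))
  out <- mc_step(m, rep(0, 12), thermo_params(t_a = 0, k1 = 0.3))
  expect_true(identical(sizes_of_membership(out), c(10L, 2L)) ||
              identical(sizes_of_membership(out), c(8L, 4L)) ||
              identical(sizes_of_membership(out), c(6L, 6L)))
  expect_equal(sum(sizes_of_membership(out)), 12L)
})

test_that("partition sizes always sum to N over many random steps", {
  th <- thermo_params(t_a = 20, k1 = 0.3)
  withr::with_seed(3, {
    g <- runif(12, 0, 5)
    m <- rep(1L, 12)
    ok <- TRUE
    for (i in seq_len(2000)) {
      m <- mc_step(m, g, th)
      if (sum(sizes_of_membership(m)) != 12L) ok <- FALSE
    }
    expect_true(ok)
    # and over a long compiled run: every iteration's recorded sizes are a
    # valid partition of 12 (group counts sum(1/n_i) are whole numbers)
    sizes <- huddlesoc:::run_mc_cpp(rep(1L, 12), g, 20, 37, 0.3, 100000)
    expect_true(all(sizes >= 1 & sizes <= 12))
    n_groups <- rowSums(1 / sizes)
    expect_true(all(abs(n_groups - round(n_groups)) < 1e-9))
    expect_true(all(n_groups >= 1 & n_groups <= 12))
  })
})

test_that("trajectories record area, body temperature and huddling", {
  cfg <- fast_mc_cfg(t_a = 10, t = 50)
  withr::with_seed(1, {
    g <- runif(12, 0, 5)
    traj <- run_mc(cfg, g)
  })
  expect_s3_class(traj, "mc_trajectory")
  expect_equal(nrow(traj), 50 * 12)
  expect_equal(traj$a, traj$group_size^(-0.25))
  expect_equal(traj$t_b,
               10 + traj$g / (traj$a * 0.3))
  # h bounds: between all-singletons (0) and one-group (1 - N^(-1/4))
  expect_true(all(traj$h >= 0 & traj$h <= 1 - 12^(-0.25) + 1e-12))
  # empty trajectory
  cfg0 <- mc_config(n = 12, t = 0, thermo = thermo_params(t_a = 10),
                    burn_in = 0)
  expect_error(mc_config(t = 0, burn_in = 1))
  traj0 <- run_mc(cfg0, g = rep(1, 12))
  expect_equal(nrow(traj0), 0)
})

test_that("metrics summarise huddling, pup flow and thermoregulation", {
  # hand-built two-iteration trajectory with h = 0.2 then 0.4
  traj <- tibble::tibble(
    iteration = rep(1:2, each = 2),
    individual = rep(1:2, times = 2),
    group_size = c(1L, 1L, 2L, 2L),
    g = 1, a = c(1, 1, 2^-0.25, 2^-0.25),
    t_b = c(11, 12, 13, 14),
    h = c(0.2, 0.2, 0.4, 0.4)
  )
  m <- mc_metrics(traj, burn_in = 0)
  expect_equal(m$h_mean, 0.3)
  expect_equal(m$pup_flow, 0.1) # population SD
  expect_equal(m$groups_mean, 1.5)
  expect_equal(m$t_b_mean, 12.5)
  expect_equal(m$t_b_individual[[1]], c(12, 13))
  # constant trajectory has zero pup flow
  traj$h <- 0.25
  expect_equal(mc_metrics(traj, burn_in = 0)$pup_flow, 0)
  expect_error(mc_metrics(traj, burn_in = 2), "burn-in")
})

test_that("cold runs plateau near maximal huddling; hot runs disperse", {
  cfg <- mc_config(n = 12, t = 5000, thermo = thermo_params(t_a = 0, k1 = 0.3))
  withr::with_seed(11, {
    g <- runif(12, 0, 5)
    m_cold <- mc_metrics(run_mc(cfg, g))
    cfg$thermo$t_a <- 50
    m_hot <- mc_metrics(run_mc(cfg, g))
  })
  expect_gt(m_cold$h_mean, 0.35)
  expect_lt(abs(m_cold$h_mean - (1 - 12^(-0.25))), 0.1)
  expect_lt(m_hot$h_mean, 0.05)
  expect_gt(m_hot$groups_mean, 10)
})

test_that("burn-in does not change the sweep's qualitative conclusions", {
  cfg <- mc_config(n = 12, t = 2000, thermo = thermo_params(t_a = 0, k1 = 0.3))
  withr::with_seed(5, {
    g <- runif(12, 0, 5)
    traj <- run_mc(cfg, g)
  })
  m0 <- mc_metrics(traj, burn_in = 0)
  m10 <- mc_metrics(traj, burn_in = 200)
  expect_equal(m0$h_mean, m10$h_mean, tolerance = 0.05)
  expect_gt(m10$h_mean, 0.35)
})

test_that("temperature sweep composes one run per temperature", {
  cfg <- fast_mc_cfg(t = 300)
  withr::with_seed(2, sw <- mc_temperature_sweep(cfg, c(0, 25, 50)))
  expect_equal(nrow(sw), 3)
  expect_named(sw, c("t_a", "replicate", "h_mean", "pup_flow", "groups_mean",
                     "t_b_mean"))
  expect_true(all(diff(sw$h_mean) < 0))
  expect_error(mc_temperature_sweep(cfg, numeric(0)))
})
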