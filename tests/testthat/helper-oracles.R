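# Shared oracles and fixture builders (all generated in code).

# Exhaustive pair-selection probabilities for a fixed partition:
# P(a = i) = n_i / N summed over a group; P(b in group J | a) = n_J / (N - n_a).
# Returns a matrix p[ga, gb] over group indices of the given sizes.
enumerate_pair_probs <- function(sizes) {
  n <- sum(sizes)
  k <- length(sizes)
  p <- matrix(0, k, k)
  for (ga in seq_len(k)) {
    pa <- sizes[ga] / n
    for (gb in seq_len(k)) {
      if (gb == ga) next
      p[ga, gb] <- pa * sizes[gb] / (n - sizes[ga])
    }
  }
  p
}

# Brute-force connected components of the contact graph by breadth-first
# search (oracle for label_groups).
bfs_components <- function(x, y, radius, slack) {
  n <- length(x)
  thr <- 2 * radius * (1 + slack)
  lab <- rep(0L, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (lab[s] > 0) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      for (j in seq_len(n)) {
        if (lab[j] == 0 &&
            sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) < thr) {
          lab[j] <- comp
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# Inverse-CDF sampler for a truncated power-law density f(x) ~ x^mu on
# [lo, hi] (mu != -1), used to test exponent recovery.
rpowerlaw <- function(n, mu, lo, hi) {
  u <- runif(n)
  a <- mu + 1
  (lo^a + u * (hi^a - lo^a))^(1 / a)
}

# Minimal evolution-trace stand-in for histogram/fit tests
trace_of <- function(g_min) {
  tibble::tibble(generation = seq_along(g_min), g_min = g_min)
}

# Membership vector with the given group sizes, labels 1..k
membership_of_sizes <- function(sizes) {
  rep(seq_along(sizes), times = sizes)
}

# group sizes (sorted) from a membership vector
sizes_of_membership <- function(m) {
  sort(as.integer(table(m)), decreasing = TRUE)
}

fast_mc_cfg <- function(t_a = 10, t = 200, n = 12, k1 = 0.3) {
  mc_config(n = n, t = t, thermo = thermo_params(t_a = t_a, k1 = k1))
}

fast_abm_cfg <- function(t_a = 10, t = 100, n = 12, ...) {
  abm_config(n = n, t = t,
             thermo = thermo_params(t_a = t_a, k1 = 1, alpha = 3), ...)
}
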