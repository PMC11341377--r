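test_that("order parameters match direct complex sums", {
  N <- 21
  same <- matrix(0.7, nrow = N, ncol = 3)
  op <- order_parameters(same)
  expect_equal(op$r1, rep(1, 3))
  expect_equal(op$r2, rep(1, 3))
  splay <- matrix(seq(-pi, pi, length.out = N + 1)[-1], ncol = 1)
  ops <- order_parameters(splay)
  expect_lt(ops$r1, 1e-12)
  expect_lt(ops$r2, 1e-12)
  # two antipodal clusters of 10 and 11
  anti <- matrix(c(rep(0, 10), rep(pi, 11)), ncol = 1)
  opa <- order_parameters(anti)
  expect_equal(opa$r1, 1 / 21, tolerance = 1e-12)
  expect_equal(opa$r2, 1, tolerance = 1e-12)
  # invariance of a splay state's r1 under a global rotation
  expect_equal(order_parameters(splay + 1.234)$r1, ops$r1, tolerance = 1e-12)
})

test_that("firing rate counts spikes in a sliding window and conserves totals", {
  # one neuron firing periodically: long-window rate tends to f / N * N = f
  f <- 2.5
  st <- ksreduce:::new_spike_train(rep(1L, 100), seq(0.4, by = 1 / f,
                                                     length.out = 100), 1L, 45)
  rate <- firing_rate(st, window = 10, times = c(20.01, 30.01, 40.01))
  expect_equal(rate, rep(f, 3), tolerance = 0.01)
  # empty train
  empty <- ksreduce:::new_spike_train(integer(0), numeric(0), 3L, 10)
  expect_equal(firing_rate(empty, 1, 1:5), rep(0, 5))
  # synchronized population: peaks of height 1/window at spike times
  N <- 21
  sync <- ksreduce:::new_spike_train(rep(1:N, 4), rep(c(2, 4, 6, 8), each = N),
                                     N, 10)
  dt <- 0.05
  r <- firing_rate(sync, dt, c(2, 3, 4.01))
  expect_equal(r, c(1 / dt, 0, 1 / dt))
  # conservation: non-overlapping windows (with boundaries off the
  # spike times) sum to the total count
  times <- seq(0.02, 10.02, by = dt)
  expect_equal(sum(firing_rate(sync, dt, times)) * N * dt, nrow(sync))
  expect_error(firing_rate(sync, -1, 1), "window")
})

test_that("circular single-linkage clustering finds sizes and handles wraparound", {
  expect_equal(detect_clusters(c(0, 0.01, 0.02, pi), tolerance = 0.05), c(3L, 1L))
  expect_equal(detect_clusters(rep(1.1, 8), tolerance = 0.05), 8L)
  # cluster straddling the +/- pi seam
  expect_equal(detect_clusters(c(pi - 0.01, -pi + 0.01, 1), tolerance = 0.05),
               c(2L, 1L))
  # near-cyclops configuration
  ph <- make_initial_phases(21, "near_cyclops", seed = 5, perturbation = 0)
  expect_equal(detect_clusters(ph, 0.05), c(10L, 10L, 1L))
  # perturbation below the tolerance keeps the pattern
  ph2 <- make_initial_phases(21, "near_cyclops", seed = 5, perturbation = 0.01)
  expect_equal(detect_clusters(ph2, 0.05), c(10L, 10L, 1L))
})

make_phase_traj <- function(phases_over_time, tag = "winfree_phase", Omega = 2.6) {
  ksreduce:::new_trajectory(seq_len(ncol(phases_over_time)) * 0.1,
                            phases_over_time,
                            rep(NA_real_, ncol(phases_over_time)),
                            tag, Omega = Omega, N = nrow(phases_over_time))
}

test_that("regime classification follows the order-parameter and cluster criteria", {
  N <- 21
  nt <- 100
  # synchronized: all phases drift together
  drift <- matrix(rep(seq(0, 1, length.out = nt), each = N), nrow = N) +
    matrix(stats::rnorm(N * nt, sd = 0.005), nrow = N)
  expect_equal(classify_regime(make_phase_traj(drift))$label, "synchronized")
  # splay: phases equally spaced, rotating
  splay <- outer(seq(-pi, pi, length.out = N + 1)[-1], rep(1, nt)) +
    matrix(rep(seq(0, 2, length.out = nt), each = N), nrow = N)
  expect_equal(classify_regime(make_phase_traj(wrap_angle(splay)))$label,
               "generalized_splay")
  # cyclops: persistent (10, 10, 1) pattern
  base <- make_initial_phases(N, "near_cyclops", seed = 2, perturbation = 0.005)
  cyc <- outer(base, rep(1, nt))
  rep_cyc <- classify_regime(make_phase_traj(wrap_angle(cyc)))
  expect_equal(rep_cyc$label, "cyclops")
  expect_equal(rep_cyc$cluster_sizes, c(10L, 10L, 1L))
  # intermediate coherence: other
  mid <- matrix(c(rep(0, 14), seq(-pi, pi, length.out = 7)), nrow = N,
                ncol = nt)
  expect_equal(classify_regime(make_phase_traj(mid))$label, "other")
})

test_that("classification is invariant under neuron relabelling", {
  N <- 21
  nt <- 60
  base <- make_initial_phases(N, "near_cyclops", seed = 9, perturbation = 0.005)
  cyc <- outer(base, rep(1, nt))
  perm <- sample(N)
  a <- classify_regime(make_phase_traj(cyc))
  b <- classify_regime(make_phase_traj(cyc[perm, ]))
  expect_equal(a$label, b$label)
  expect_equal(a$cluster_sizes, b$cluster_sizes)
  expect_equal(a$r1_longtime_mean, b$r1_longtime_mean)
})

test_that("theta trajectories are classified after mapping to the rotating phase", {
  N <- 10
  nt <- 50
  sync_theta <- matrix(0.4, nrow = N, ncol = nt)
  traj <- make_phase_traj(sync_theta, tag = "theta", Omega = 2.64)
  expect_equal(classify_regime(traj)$label, "synchronized")
  traj_no_omega <- make_phase_traj(sync_theta, tag = "theta", Omega = NULL)
  expect_error(classify_regime(traj_no_omega), "Omega")
})
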