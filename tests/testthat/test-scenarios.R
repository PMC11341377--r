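test_that("current generator respects support, mean and determinism", {
  expect_equal(make_eta(21, 2, 0, seed = 99), rep(2, 21))
  e <- make_eta(21, 2, 6e-3, seed = 11)
  expect_true(all(e >= 2 - 3e-3 & e <= 2 + 3e-3))
  expect_identical(e, make_eta(21, 2, 6e-3, seed = 11))
  expect_false(identical(e, make_eta(21, 2, 6e-3, seed = 12)))
  # sample mean within a few standard errors of the uniform mean
  big <- make_eta(2000, 2, 6e-3, seed = 1)
  expect_lt(abs(mean(big) - 2), 3 * 6e-3 / sqrt(12 * 2000))
  expect_error(make_eta(5, 0.1, 0.3, seed = 1), "positive")
})

test_that("initial-phase generator produces the advertised structures", {
  u <- make_initial_phases(21, "uniform", seed = 3)
  expect_identical(u, make_initial_phases(21, "uniform", seed = 3))
  expect_true(all(u >= -pi & u <= pi))
  expect_error(make_initial_phases(20, "near_cyclops", seed = 1), "odd")
  cyc <- make_initial_phases(21, "near_cyclops", seed = 1, perturbation = 0)
  expect_equal(detect_clusters(cyc, 0.05), c(10L, 10L, 1L))
  # exact cyclops placement has vanishing first-order order parameter
  expect_lt(Mod(mean(exp(1i * cyc))), 1e-12)
  expect_equal(unname(make_initial_phases(5, "near_sync", seed = 1,
                                          perturbation = 0)), rep(0, 5))
})

test_that("bundled scenarios carry the working-point parameters", {
  A <- scenario_preset("A")
  expect_equal(A$kernel$q, 2L)
  expect_equal(A$kernel$tau, 0.5)
  expect_equal(A$nu, 20)
  expect_equal(A$delta_eta, 6e-3)
  expect_equal(A$kappa, -0.2 * pi)
  B <- scenario_preset("B")
  expect_equal(B$kernel$tau, 0.8)
  expect_equal(B$delta_eta, 1e-3)
  C <- scenario_preset("C")
  expect_equal(C$kernel$q, 4L)
  expect_equal(C$kernel$tau, 0.15)
  D <- scenario_preset("D")
  expect_equal(D$kernel$tau, 0.41)
  cy <- scenario_preset("cyclops")
  expect_identical(cy$nu, Inf)
  expect_equal(cy$delta_eta, 0)
  expect_equal(cy$init_mode, "near_cyclops")
})

test_that("an uncoupled scenario runs every model and produces closed-form rates", {
  sc <- scenario("free", N = 5, eta_mean = 2, delta_eta = 0, kappa = 0,
                 nu = 20, q = 0, tau = 1, T = 40,
                 models = c("theta", "winfree", "ks", "qif"))
  rep <- run_scenario(sc, seed = 2)
  expect_setequal(names(rep$runs), c("theta", "winfree", "ks", "qif"))
  # uncoupled, identical currents: every model drifts incoherently
  for (m in names(rep$labels)) {
    expect_true(rep$labels[[m]] %in% c("other", "generalized_splay"))
  }
  # spike count per neuron matches the closed-form rate sqrt(2)/pi
  n_sp <- sum(rep$runs$theta$spikes$neuron == 1)
  expect_lte(abs(n_sp - 40 * sqrt(2) / pi), 1.5)
})

test_that("identical configuration and seed give bitwise-identical outputs", {
  sc <- scenario("det", N = 5, eta_mean = 2, delta_eta = 6e-3, kappa = -0.3,
                 nu = 20, q = 2, tau = 0.5, T = 10, models = c("theta", "ks"))
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  r1 <- run_scenario(sc, seed = 5, out_dir = d1)
  r2 <- run_scenario(sc, seed = 5, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("scenario configs round-trip through YAML", {
  cfg <- system.file("extdata", "scenario_A.yaml", package = "ksreduce")
  expect_true(nzchar(cfg))
  sc <- read_scenario_config(cfg)
  ref <- scenario_preset("A")
  for (f in c("N", "eta_mean", "delta_eta", "kappa", "nu", "T", "dt",
              "init_mode", "models", "expected_regime")) {
    expect_equal(sc[[f]], ref[[f]], label = f)
  }
  expect_equal(sc$kernel, ref$kernel)
  # delta-pulse scenario: nu comes back as Inf
  cy <- read_scenario_config(system.file("extdata", "scenario_cyclops.yaml",
                                         package = "ksreduce"))
  expect_identical(cy$nu, Inf)
})

test_that("exports carry metadata and read back cleanly", {
  k <- synaptic_kernel(2, 0.5)
  ks <- reduce_to_ks(network_params(rep(2, 5), -0.2 * pi, 20, k))
  f <- tempfile(fileext = ".json")
  write_ks_params(ks, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$Omega, ks$Omega, tolerance = 1e-12)
  expect_false(back$attractive && ks$K * cos(ks$alpha) < 0)
  m <- region_map(2, -0.2 * pi, 20, tau_grid = c(0.5, 0.8), eta_grid = c(1.5, 2))
  f2 <- tempfile(fileext = ".csv")
  write_region_map(m, f2)
  df <- utils::read.csv(f2, comment.char = "#")
  expect_equal(nrow(df), 4L)
  expect_equal(sort(unique(df$tau)), c(0.5, 0.8))
  f3 <- tempfile(fileext = ".csv")
  write_pulse_coefficients(20, 2, ell_max = 3, path = f3)
  qc <- utils::read.csv(f3, comment.char = "#")
  expect_equal(qc$value[1], 1 / pi, tolerance = 1e-10)
  expect_equal(qc$ell, 0:3)
  unlink(c(f, f2, f3))
})
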