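# CSV/JSON export and config reading. All CSV writers prepend comment
# metadata lines ("# key: value") that read.csv skips with
# comment.char = "#".

write_metadata_csv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta),
                     vapply(meta, format, character(1))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

pkg_meta <- function(...) {
  c(list(package = "ksreduce",
         version = as.character(utils::packageVersion("ksreduce"))),
    list(...))
}

#' Write a spike train to CSV
#'
#' Columns `neuron_id`, `time`, preceded by comment metadata lines.
#'
#' @param spikes A spike train.
#' @param path Output file.
#' @export
write_spike_train <- function(spikes, path) {
  write_metadata_csv(
    data.frame(neuron_id = spikes$neuron, time = spikes$time),
    path,
    pkg_meta(kind = "spike_train", N = attr(spikes, "N"),
             horizon = attr(spikes, "horizon"))
  )
}

#' Write a trajectory to long-format CSV
#'
#' Columns `time`, `neuron_id`, `value`, with the synaptic series
#' appended as `neuron_id = 0`.
#'
#' @param trajectory A `trajectory` object.
#' @param path Output file.
#' @export
write_trajectory <- function(trajectory, path) {
  nt <- length(trajectory$times)
  df <- data.frame(
    time = rep(trajectory$times, each = trajectory$N),
    neuron_id = rep(seq_len(trajectory$N), times = nt),
    value = as.vector(trajectory$states)
  )
  if (!all(is.na(trajectory$synaptic))) {
    df <- rbind(df, data.frame(time = trajectory$times, neuron_id = 0L,
                               value = trajectory$synaptic))
  }
  write_metadata_csv(df, path,
                     pkg_meta(kind = "trajectory", model = trajectory$model_tag,
                              N = trajectory$N))
}

#' Write reduced model parameters to JSON
#'
#' @param ks A `ks_params` object.
#' @param path Output file.
#' @export
write_ks_params <- function(ks, path) {
  jsonlite::write_json(
    list(Omega = ks$Omega, K = ks$K, alpha = ks$alpha,
         omega = ks$omega, Q0 = ks$Q0, Q1 = ks$Q1,
         G1 = c(Re = Re(ks$G1), Im = Im(ks$G1)),
         attractive = ks$K * cos(ks$alpha) > 0),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a coupling region map to long-format CSV
#'
#' Columns `tau`, `eta`, `q`, `attractive`.
#'
#' @param map A `coupling_region_map`.
#' @param path Output file.
#' @export
write_region_map <- function(map, path) {
  df <- expand.grid(tau = map$tau_grid, eta = map$eta_grid,
                    KEEP.OUT.ATTRS = FALSE)
  df$q <- map$q
  df$attractive <- as.vector(map$attractive)
  write_metadata_csv(df, path,
                     pkg_meta(kind = "region_map", kappa = map$kappa,
                              nu = map$nu))
}

#' Write order-parameter series to CSV
#'
#' @param series An `order_parameter_series` data frame.
#' @param path Output file.
#' @export
write_order_parameters <- function(series, path) {
  write_metadata_csv(as.data.frame(series), path,
                     pkg_meta(kind = "order_parameters"))
}

#' Write pulse Fourier coefficients to CSV
#'
#' Tabulates \eqn{Q_{\nu\ell}} for harmonics `0:ell_max` at a given
#' sharpness and rotation frequency (columns `ell`, `value`).
#'
#' @param nu Positive integer sharpness, or `Inf` for the delta limit.
#' @param Omega Positive rotation frequency.
#' @param ell_max Largest harmonic index.
#' @param path Output file.
#' @export
write_pulse_coefficients <- function(nu, Omega, ell_max, path) {
  stopifnot(ell_max >= 0, ell_max == round(ell_max))
  ells <- 0:ell_max
  vals <- vapply(ells, function(l) {
    if (is.infinite(nu)) delta_limit_coefficient(l, Omega)$value
    else pulse_fourier(l, nu, Omega)$value
  }, numeric(1))
  write_metadata_csv(data.frame(ell = ells, value = vals), path,
                     pkg_meta(kind = "pulse_coefficients", nu = nu,
                              Omega = Omega))
}

write_comparison_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- report$scenario
  write_ks_params(report$ks, file.path(out_dir, "ks_params.json"))
  for (m in names(report$runs)) {
    run <- report$runs[[m]]
    write_trajectory(run$trajectory,
                     file.path(out_dir, sprintf("trajectory_%s.csv", m)))
    write_spike_train(run$spikes,
                      file.path(out_dir, sprintf("spikes_%s.csv", m)))
    write_order_parameters(order_parameters(run$trajectory),
                           file.path(out_dir, sprintf("order_parameters_%s.csv", m)))
  }
  regimes <- lapply(report$regimes, function(r) {
    list(label = r$label, cluster_sizes = r$cluster_sizes,
         r1_longtime_mean = r$r1_longtime_mean,
         r2_longtime_mean = r$r2_longtime_mean,
         cyclops_fraction = r$cyclops_fraction,
         settings = r$settings)
  })
  jsonlite::write_json(
    list(scenario = sc$name, seed = report$seed,
         labels = as.list(report$labels),
         expected_regime = sc$expected_regime,
         regimes = regimes,
         stats = report$stats),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' Read a scenario from a YAML or JSON config file
#'
#' The config mirrors the [scenario()] arguments, with the kernel given
#' as a block `kernel: {family: gamma, q: ..., tau: ...}`. `nu` may be
#' the string `"Inf"` for delta pulses.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A [scenario()] object.
#' @export
read_scenario_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  required <- c("name", "N", "eta_mean", "kappa", "nu", "kernel")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config lacks required fields: ", paste(missing, collapse = ", "))
  }
  if (!identical(cfg$kernel$family, "gamma")) {
    stop("only gamma-family kernel blocks are supported in scenario configs")
  }
  nu <- if (is.character(cfg$nu)) as.numeric(cfg$nu) else cfg$nu
  arg <- list(
    name = cfg$name, N = cfg$N, eta_mean = cfg$eta_mean,
    delta_eta = cfg$delta_eta %||% 0, kappa = cfg$kappa, nu = nu,
    q = cfg$kernel$q, tau = cfg$kernel$tau
  )
  for (f in c("T", "dt", "init_mode", "perturbation", "models", "v_th",
              "expected_regime")) {
    if (!is.null(cfg[[f]])) arg[[f]] <- cfg[[f]]
  }
  do.call(scenario, arg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
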