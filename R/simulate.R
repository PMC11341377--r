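# Fixed-step integration of the three model levels. The smooth phase
# models (theta, Winfree-form, Kuramoto-Sakaguchi) use classical
# fourth-order Runge-Kutta. The QIF membrane equation v' = v^2 + c blows
# up in finite time near threshold, so each step propagates it with the
# exact solution of the frozen-coefficient Riccati equation (c held at
# its midpoint value), which handles v_th = 1e5 without overshoot and
# yields threshold-crossing times in closed form.

new_trajectory <- function(times, states, synaptic, model_tag,
                           Omega = NULL, N = nrow(states)) {
  structure(
    list(times = times, states = states, synaptic = synaptic,
         model_tag = model_tag, Omega = Omega, N = N),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> model = %s, N = %d, %d samples on [%g, %g]\n",
    x$model_tag, x$N, length(x$times), min(x$times), max(x$times)
  ))
  invisible(x)
}

new_spike_train <- function(neuron, time, N, T) {
  o <- order(time, neuron)
  structure(
    data.frame(neuron = as.integer(neuron[o]), time = as.numeric(time[o])),
    class = c("spike_train", "data.frame"),
    N = N, horizon = T
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes from %d neurons on [0, %g]\n",
              nrow(x), attr(x, "N"), attr(x, "horizon")))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 5))
  invisible(x)
}

#' Integration settings for the network simulators
#'
#' @param dt Integration step (default 0.01 time units).
#' @param T Horizon.
#' @param keep_every Store every `keep_every`-th sample in the returned
#'   trajectory (spike detection inside the simulators always works at
#'   the full step resolution).
#' @return A list of class `integration_settings`.
#' @export
integration_settings <- function(dt = 0.01, T = 200, keep_every = 10L) {
  stopifnot(dt > 0, T > dt, keep_every >= 1L)
  structure(list(dt = dt, T = T, keep_every = as.integer(keep_every)),
            class = "integration_settings")
}

# upward crossings of the level lines pi + 2 pi k between two unwrapped
# phase samples; returns interpolated crossing offsets in [0, h]
phase_crossings <- function(th_old, th_new, h) {
  k_old <- floor((th_old - pi) / (2 * pi))
  k_new <- floor((th_new - pi) / (2 * pi))
  idx <- which(k_new > k_old)
  if (length(idx) == 0L) return(NULL)
  # first crossed level for each neuron (multiple crossings per step do
  # not occur at sensible step sizes)
  lev <- (k_old[idx] + 1) * 2 * pi + pi
  list(neuron = idx,
       offset = h * (lev - th_old[idx]) / (th_new[idx] - th_old[idx]))
}

# shared RK4 driver for the phase models with a continuous pulse drive
# feeding the synaptic cascade
integrate_pulse_network <- function(state0, nstage, deriv, dt, nsteps,
                                    keep_every) {
  N <- length(state0) - nstage
  nkeep <- nsteps %/% keep_every + 1L
  states <- matrix(NA_real_, nrow = N, ncol = nkeep)
  syn <- numeric(nkeep)
  times <- numeric(nkeep)
  states[, 1] <- state0[seq_len(N)]
  syn[1] <- state0[length(state0)]
  spk_n <- integer(0)
  spk_t <- numeric(0)
  y <- state0
  col <- 2L
  for (s in seq_len(nsteps)) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y_new <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    cr <- phase_crossings(y[seq_len(N)], y_new[seq_len(N)], dt)
    if (!is.null(cr)) {
      spk_n <- c(spk_n, cr$neuron)
      spk_t <- c(spk_t, (s - 1) * dt + cr$offset)
    }
    y <- y_new
    if (s %% keep_every == 0L) {
      states[, col] <- y[seq_len(N)]
      syn[col] <- y[length(y)]
      times[col] <- s * dt
      col <- col + 1L
    }
  }
  list(times = times, states = states, synaptic = syn,
       spk_n = spk_n, spk_t = spk_t)
}

# phase models in the delta-pulse limit: the cascade is driven by spike
# impulses instead of a continuous pulse profile, and is propagated
# exactly between impulses
integrate_delta_network <- function(phase0, phase_deriv, kernel, N, dt,
                                    nsteps, keep_every) {
  q <- kernel$q
  tau <- kernel$tau
  u <- numeric(q + 1)
  nkeep <- nsteps %/% keep_every + 1L
  states <- matrix(NA_real_, nrow = N, ncol = nkeep)
  syn <- numeric(nkeep)
  times <- numeric(nkeep)
  states[, 1] <- phase0
  spk_n <- integer(0)
  spk_t <- numeric(0)
  th <- phase0
  col <- 2L
  for (s in seq_len(nsteps)) {
    # synaptic output at the RK4 stage offsets, from the exact
    # homogeneous solution of the cascade
    S0 <- u[q + 1]
    Sh <- cascade_propagate(u, dt / (2 * tau))[q + 1]
    S1 <- cascade_propagate(u, dt / tau)[q + 1]
    k1 <- phase_deriv(th, S0)
    k2 <- phase_deriv(th + dt / 2 * k1, Sh)
    k3 <- phase_deriv(th + dt / 2 * k2, Sh)
    k4 <- phase_deriv(th + dt * k3, S1)
    th_new <- th + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    u <- cascade_propagate(u, dt / tau)
    cr <- phase_crossings(th, th_new, dt)
    if (!is.null(cr)) {
      spk_n <- c(spk_n, cr$neuron)
      spk_t <- c(spk_t, (s - 1) * dt + cr$offset)
      # impulses applied at the end of the containing step
      u[1] <- u[1] + length(cr$neuron) / (N * tau)
    }
    th <- th_new
    if (s %% keep_every == 0L) {
      states[, col] <- th
      syn[col] <- u[q + 1]
      times[col] <- s * dt
      col <- col + 1L
    }
  }
  list(times = times, states = states, synaptic = syn,
       spk_n = spk_n, spk_t = spk_t)
}

#' Simulate the theta-neuron network
#'
#' Integrates
#' \deqn{\dot\theta_n = (1 - \cos\theta_n) +
#'   (1 + \cos\theta_n)(\eta_n + \varkappa S)}
#' with the synaptic activity `S` generated by the linear cascade driven
#' by the population mean pulse \eqn{\frac1N\sum P_\nu(\theta_{n'})}
#' (finite `nu`), or by spike impulses of weight `1/(N tau)` in the
#' delta-pulse limit (`nu = Inf`). A neuron spikes when its phase
#' crosses \eqn{\pi} upward; spike times are interpolated within the
#' step.
#'
#' @param params A [network_params()] object.
#' @param theta0 Initial phases, length N.
#' @param settings An [integration_settings()] object.
#' @return A list with elements `trajectory` (phases wrapped to
#'   \eqn{(-\pi,\pi]}, plus the synaptic series) and `spikes` (a spike
#'   train).
#' @export
simulate_theta <- function(params, theta0,
                           settings = integration_settings()) {
  stopifnot(inherits(params, "network_params"),
            length(theta0) == params$N,
            inherits(settings, "integration_settings"))
  if (!is_gamma_kernel(params$kernel)) {
    stop("network simulation requires a gamma-family kernel (cascade form)")
  }
  check_step_size(settings$dt, params)
  N <- params$N
  eta <- params$eta
  kap <- params$kappa
  tau <- params$kernel$tau
  q <- params$kernel$q
  nsteps <- round(settings$T / settings$dt)
  theta_rhs <- function(th, S) {
    (1 - cos(th)) + (1 + cos(th)) * (eta + kap * S)
  }
  res <- if (is.infinite(params$nu)) {
    integrate_delta_network(theta0, theta_rhs, params$kernel, N,
                            settings$dt, nsteps, settings$keep_every)
  } else {
    nu <- params$nu
    idx <- seq_len(N)
    uidx <- N + seq_len(q + 1)
    deriv <- function(y) {
      th <- y[idx]
      u <- y[uidx]
      c(theta_rhs(th, u[q + 1]),
        cascade_deriv(u, mean(pulse_value(th, nu)), tau))
    }
    integrate_pulse_network(c(theta0, numeric(q + 1)), q + 1, deriv,
                            settings$dt, nsteps, settings$keep_every)
  }
  finish_phase_sim(res, "theta", N, settings, Omega = NULL)
}

#' Simulate the Winfree-form phase network
#'
#' Integrates the uniformly rotating phase representation
#' \deqn{\dot\varphi_n = \Omega + \frac{2}{\Omega}(1 + \cos\varphi_n)
#'   \left(\eta_n - \Omega^2/4 + \varkappa S\right)}
#' with the cascade driven by the mean transformed pulse
#' \eqn{Q_\nu(\varphi)} (finite `nu`) or by spike impulses
#' (`nu = Inf`). Trajectories map to [simulate_theta()] output under the
#' variable change \eqn{2\tan(\theta/2) = \Omega\tan(\varphi/2)} within
#' integration error; at \eqn{\Omega = 2} the two models coincide.
#'
#' @param params A [network_params()] object.
#' @param phi0 Initial phases, length N.
#' @param Omega Fast rotation frequency; if `NULL`, computed with
#'   [solve_omega()].
#' @param settings An [integration_settings()] object.
#' @return As [simulate_theta()].
#' @export
simulate_winfree_phase <- function(params, phi0, Omega = NULL,
                                   settings = integration_settings()) {
  stopifnot(inherits(params, "network_params"),
            length(phi0) == params$N,
            inherits(settings, "integration_settings"))
  if (!is_gamma_kernel(params$kernel)) {
    stop("network simulation requires a gamma-family kernel (cascade form)")
  }
  check_step_size(settings$dt, params)
  if (is.null(Omega)) {
    Omega <- solve_omega(mean(params$eta), params$kappa, params$nu)
  }
  N <- params$N
  eta <- params$eta
  kap <- params$kappa
  tau <- params$kernel$tau
  q <- params$kernel$q
  nsteps <- round(settings$T / settings$dt)
  phi_rhs <- function(ph, S) {
    Omega + (2 / Omega) * (1 + cos(ph)) * (eta - Omega^2 / 4 + kap * S)
  }
  res <- if (is.infinite(params$nu)) {
    integrate_delta_network(phi0, phi_rhs, params$kernel, N,
                            settings$dt, nsteps, settings$keep_every)
  } else {
    nu <- params$nu
    idx <- seq_len(N)
    uidx <- N + seq_len(q + 1)
    deriv <- function(y) {
      ph <- y[idx]
      u <- y[uidx]
      c(phi_rhs(ph, u[q + 1]),
        cascade_deriv(u, mean(transformed_pulse_value(ph, nu, Omega)), tau))
    }
    integrate_pulse_network(c(phi0, numeric(q + 1)), q + 1, deriv,
                            settings$dt, nsteps, settings$keep_every)
  }
  finish_phase_sim(res, "winfree_phase", N, settings, Omega = Omega)
}

finish_phase_sim <- function(res, tag, N, settings, Omega) {
  traj <- new_trajectory(res$times, wrap_angle(res$states), res$synaptic,
                         tag, Omega = Omega, N = N)
  spikes <- new_spike_train(res$spk_n, res$spk_t, N, settings$T)
  list(trajectory = traj, spikes = spikes)
}

#' Simulate the Kuramoto-Sakaguchi model
#'
#' Integrates the reduced slow-phase model
#' \deqn{\dot\phi_n = \omega_n + \frac{K}{N}\sum_{n'}
#'   \sin(\phi_{n'} - \phi_n - \alpha)}
#' with fixed-step RK4, using the mean-field form of the coupling sum.
#' The stored trajectory holds the slow phases \eqn{\phi_n};
#' [detect_spikes()] reconstructs the fast phase
#' \eqn{\varphi_n = \Omega t + \phi_n} to locate firing times.
#'
#' @param ks A `ks_params` object from [reduce_to_ks()], or a list with
#'   fields `omega`, `K`, `alpha`, `Omega`.
#' @param phi0 Initial slow phases, length N.
#' @param settings An [integration_settings()] object.
#' @return A list with `trajectory` (slow phases, wrapped) and `spikes`
#'   (from the reconstructed fast phase).
#' @export
simulate_ks <- function(ks, phi0, settings = integration_settings()) {
  stopifnot(!is.null(ks$omega), !is.null(ks$K), !is.null(ks$alpha),
            inherits(settings, "integration_settings"))
  N <- length(ks$omega)
  stopifnot(length(phi0) == N)
  omega <- ks$omega
  K <- ks$K
  alpha <- ks$alpha
  Omega <- ks$Omega
  dt <- settings$dt
  nsteps <- round(settings$T / dt)
  keep_every <- settings$keep_every
  deriv <- function(p) {
    Z <- mean(exp(1i * p))
    omega + K * Mod(Z) * sin(Arg(Z) - p - alpha)
  }
  nkeep <- nsteps %/% keep_every + 1L
  states <- matrix(NA_real_, nrow = N, ncol = nkeep)
  times <- numeric(nkeep)
  states[, 1] <- phi0
  spk_n <- integer(0)
  spk_t <- numeric(0)
  p <- phi0
  col <- 2L
  for (s in seq_len(nsteps)) {
    k1 <- deriv(p)
    k2 <- deriv(p + dt / 2 * k1)
    k3 <- deriv(p + dt / 2 * k2)
    k4 <- deriv(p + dt * k3)
    p_new <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.null(Omega)) {
      cr <- phase_crossings(p + Omega * (s - 1) * dt,
                            p_new + Omega * s * dt, dt)
      if (!is.null(cr)) {
        spk_n <- c(spk_n, cr$neuron)
        spk_t <- c(spk_t, (s - 1) * dt + cr$offset)
      }
    }
    p <- p_new
    if (s %% keep_every == 0L) {
      states[, col] <- p
      times[col] <- s * dt
      col <- col + 1L
    }
  }
  traj <- new_trajectory(times, wrap_angle(states), rep(NA_real_, nkeep),
                         "ks", Omega = Omega, N = N)
  spikes <- new_spike_train(spk_n, spk_t, N, settings$T)
  list(trajectory = traj, spikes = spikes)
}

check_step_size <- function(dt, params) {
  lim <- min(params$kernel$tau / 10, 0.1 / sqrt(max(params$eta)))
  if (dt > lim) {
    warning(sprintf(
      "dt = %g exceeds the recommended bound %g (tau/10 and 0.1/sqrt(max eta))",
      dt, lim
    ))
  }
  invisible(dt)
}
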