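#' QIF simulation configuration
#'
#' @param network A [network_params()] object (the pulse sharpness `nu`
#'   is not used by the QIF model, whose spikes are intrinsically
#'   delta-like).
#' @param v_th Positive spike threshold.
#' @param v_r Negative reset potential.
#' @param settings An [integration_settings()] object.
#' @param refractory_mode `"none"` resets immediately at the
#'   threshold-crossing time; `"pass_through"` additionally holds the
#'   neuron for `1/v_th + 1/|v_r|` (the leading-order transit time
#'   through the spike singularity at finite threshold) before placing
#'   it at `v_r`.
#' @return A list of class `qif_config`.
#' @export
qif_config <- function(network, v_th = 1e5, v_r = -v_th,
                       settings = integration_settings(),
                       refractory_mode = c("none", "pass_through")) {
  stopifnot(inherits(network, "network_params"),
            inherits(settings, "integration_settings"))
  if (!is_gamma_kernel(network$kernel)) {
    stop("QIF simulation requires a gamma-family kernel (cascade form)")
  }
  stopifnot(length(v_th) == 1L, v_th > 0, length(v_r) == 1L, v_r < 0)
  refractory_mode <- match.arg(refractory_mode)
  check_step_size(settings$dt, network)
  structure(
    list(network = network, v_th = v_th, v_r = v_r, settings = settings,
         refractory_mode = refractory_mode),
    class = "qif_config"
  )
}

# Exact propagation of v' = v^2 + c over an interval s with frozen c.
# Returns the end value, or the threshold-crossing offset if v reaches
# v_th within the interval. Branches cover c > 0 (tangent solution),
# c < 0 (saddle pair at +/- sqrt(-c)) and c = 0.
qif_propagate_scalar <- function(v, c, s, v_th) {
  if (c > 1e-12) {
    sq <- sqrt(c)
    beta <- atan(v / sq)
    arg_th <- atan(v_th / sq)
    arg_end <- beta + sq * s
    if (arg_end >= arg_th) {
      return(list(crossed = TRUE, s_cross = (arg_th - beta) / sq))
    }
    list(crossed = FALSE, v = sq * tan(arg_end))
  } else if (c < -1e-12) {
    g <- sqrt(-c)
    if (v > g) {
      s_star <- log(((v_th - g) * (v + g)) / ((v_th + g) * (v - g))) / (2 * g)
      if (s_star <= s) return(list(crossed = TRUE, s_cross = s_star))
    }
    w <- (v - g) / (v + g) * exp(2 * g * s)
    list(crossed = FALSE, v = g * (1 + w) / (1 - w))
  } else {
    if (v > 0 && (1 / v - 1 / v_th) <= s) {
      return(list(crossed = TRUE, s_cross = 1 / v - 1 / v_th))
    }
    list(crossed = FALSE, v = v / (1 - v * s))
  }
}

#' Simulate the QIF network
#'
#' Integrates the membrane equations
#' \eqn{\dot v_n = v_n^2 + \eta_n + \varkappa S(t)} with reset
#' \eqn{v \leftarrow v_r} when \eqn{v} crosses \eqn{v_{th}} upward.
#' Within each fixed step the synaptic drive is frozen at its midpoint
#' value and each membrane equation is advanced with the exact solution
#' of the resulting Riccati equation, so the quadratic blow-up toward
#' threshold is handled without numerical overshoot and spike times come
#' out in closed form within the step. Every spike injects a jump of
#' `1/(N tau)` into the first cascade stage at the end of the containing
#' step, reproducing the gamma-kernel synaptic response.
#'
#' @param config A [qif_config()] object.
#' @param initial_v Initial membrane potentials (below threshold).
#' @return A list with `trajectory` (membrane potentials and synaptic
#'   series) and `spikes`.
#' @export
simulate_qif <- function(config, initial_v) {
  stopifnot(inherits(config, "qif_config"))
  net <- config$network
  N <- net$N
  stopifnot(length(initial_v) == N)
  if (any(initial_v >= config$v_th)) stop("initial voltages must be below v_th")
  dt <- config$settings$dt
  nsteps <- round(config$settings$T / dt)
  keep_every <- config$settings$keep_every
  tau <- net$kernel$tau
  q <- net$kernel$q
  v_th <- config$v_th
  v_r <- config$v_r
  hold <- if (config$refractory_mode == "pass_through") {
    1 / v_th + 1 / abs(v_r)
  } else 0
  u <- numeric(q + 1)
  v <- as.numeric(initial_v)
  held_until <- rep(-Inf, N) # neurons in transit through the singularity
  nkeep <- nsteps %/% keep_every + 1L
  states <- matrix(NA_real_, nrow = N, ncol = nkeep)
  syn <- numeric(nkeep)
  times <- numeric(nkeep)
  states[, 1] <- v
  spk_n <- integer(0)
  spk_t <- numeric(0)
  col <- 2L
  for (s in seq_len(nsteps)) {
    t0 <- (s - 1) * dt
    S_mid <- cascade_propagate(u, dt / (2 * tau))[q + 1]
    cc <- net$eta + net$kappa * S_mid
    n_spk <- 0L
    for (n in seq_len(N)) {
      start <- max(t0, held_until[n])
      if (start >= t0 + dt) next # still in transit
      span <- t0 + dt - start
      r <- qif_propagate_scalar(v[n], cc[n], span, v_th)
      if (!r$crossed) {
        v[n] <- r$v
        next
      }
      t_sp <- start + r$s_cross
      spk_n <- c(spk_n, n)
      spk_t <- c(spk_t, t_sp)
      n_spk <- n_spk + 1L
      resume <- t_sp + hold
      v[n] <- v_r
      held_until[n] <- resume
      if (resume < t0 + dt) {
        r2 <- qif_propagate_scalar(v_r, cc[n], t0 + dt - resume, v_th)
        # v_r is far from threshold; a second crossing in the same step
        # would require dt comparable to the firing period
        v[n] <- r2$v
      }
    }
    u <- cascade_propagate(u, dt / tau)
    if (n_spk > 0L) u[1] <- u[1] + n_spk / (N * tau)
    if (s %% keep_every == 0L) {
      states[, col] <- v
      syn[col] <- u[q + 1]
      times[col] <- s * dt
      col <- col + 1L
    }
  }
  traj <- new_trajectory(times, states, syn, "qif", Omega = NULL, N = N)
  spikes <- new_spike_train(spk_n, spk_t, N, config$settings$T)
  list(trajectory = traj, spikes = spikes)
}
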