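# Linear synaptic cascade: the (q+1)th-order operator (tau d/dt + 1)^(q+1)
# factorized into first-order stages
#   tau u1' + u1 = input,  tau u_{k+1}' + u_{k+1} = u_k,  S = u_{q+1}.
# Its Green's function is exactly the gamma kernel, so a spike that adds
# 1/(N tau) to the first stage contributes G(t)/N to S.

# Exact propagation of the homogeneous cascade over a dimensionless time
# s = dt/tau: the stage vector picks up the matrix exponential
#   u_j <- exp(-s) * sum_{i <= j} u_i s^(j-i) / (j-i)!
cascade_propagate <- function(u, s) {
  n <- length(u)
  fac <- exp(-s) * c(1, cumprod(s / seq_len(n - 1)))
  out <- numeric(n)
  for (j in seq_len(n)) {
    out[j] <- sum(u[seq_len(j)] * fac[j:1])
  }
  out
}

# Stage derivatives for joint RK4 integration with a continuous input.
cascade_deriv <- function(u, input, tau) {
  (c(input, u[-length(u)]) - u) / tau
}

#' Synaptic response to a single spike
#'
#' Integrates the linear synaptic cascade driven by one unit spike at
#' `t = 0` (a jump of `1/(N tau)` in the first stage) and returns the
#' output activity `S(t)` on a fixed time grid. The cascade is the
#' factorized form of the \eqn{(q+1)}th-order operator whose Green's
#' function is the gamma kernel, so the result equals
#' `gamma_kernel_value(t, kernel) / N`.
#'
#' @param kernel A gamma-family [synaptic_kernel()].
#' @param N Network size the spike is averaged over.
#' @param dt Output time step.
#' @param T Horizon.
#' @return A data frame with columns `time` and `S`.
#' @export
synaptic_impulse_response <- function(kernel, N = 1L, dt = 0.01, T = 5) {
  if (!is_gamma_kernel(kernel)) stop("`kernel` must be a gamma-family synaptic_kernel")
  stopifnot(N >= 1, dt > 0, T > dt)
  u <- numeric(kernel$q + 1)
  u[1] <- 1 / (N * kernel$tau)
  times <- seq(0, T, by = dt)
  S <- numeric(length(times))
  S[1] <- u[kernel$q + 1]
  for (i in seq_along(times)[-1]) {
    u <- cascade_propagate(u, dt / kernel$tau)
    S[i] <- u[kernel$q + 1]
  }
  data.frame(time = times, S = S)
}
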