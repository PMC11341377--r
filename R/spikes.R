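#' Detect spikes in a sampled trajectory
#'
#' Locates spike events by monitoring sign changes between consecutive
#' samples and interpolating linearly within the sampling interval. For
#' the QIF model the monitored quantity is \eqn{v - v_{th}}; for the
#' phase models it is the upward crossing of the spike phase \eqn{\pi}
#' (modulo \eqn{2\pi}), handled through wrapped phase increments so that
#' backward wraps are not mistaken for firings. For Kuramoto-Sakaguchi
#' trajectories the fast phase \eqn{\varphi_n = \Omega t + \phi_n} is
#' reconstructed first.
#'
#' Note the resolution is that of the stored samples: run the simulator
#' with `keep_every = 1` when precise spike times are needed from this
#' function (the simulators' own online detection always works at full
#' step resolution).
#'
#' @param trajectory A `trajectory` object.
#' @param v_th Threshold, required for QIF trajectories.
#' @return A spike train (`data.frame` with columns `neuron`, `time`).
#' @export
detect_spikes <- function(trajectory, v_th = NULL) {
  stopifnot(inherits(trajectory, "trajectory"))
  x <- trajectory$states
  tt <- trajectory$times
  N <- trajectory$N
  spk_n <- integer(0)
  spk_t <- numeric(0)
  if (trajectory$model_tag == "qif") {
    if (is.null(v_th)) stop("`v_th` is required for QIF trajectories")
    for (i in seq_len(ncol(x) - 1)) {
      d <- x[, i + 1] - x[, i]
      idx <- which(x[, i] < v_th & x[, i + 1] >= v_th & d > 0)
      if (length(idx)) {
        frac <- (v_th - x[idx, i]) / d[idx]
        spk_n <- c(spk_n, idx)
        spk_t <- c(spk_t, tt[i] + frac * (tt[i + 1] - tt[i]))
      }
    }
  } else {
    if (trajectory$model_tag == "ks") {
      if (is.null(trajectory$Omega)) {
        stop("KS trajectory lacks Omega; cannot reconstruct the fast phase")
      }
      x <- wrap_angle(sweep(x, 2, trajectory$Omega * tt, "+"))
    }
    # signed circular distance to the spike phase: an upward crossing
    # takes it from negative to non-negative by a small increment
    s <- wrap_angle(x - pi)
    for (i in seq_len(ncol(x) - 1)) {
      s1 <- s[, i]
      s2 <- s[, i + 1]
      d <- s2 - s1
      idx <- which(s1 < 0 & s2 >= 0 & d > 0 & d < pi)
      if (length(idx)) {
        frac <- -s1[idx] / d[idx]
        spk_n <- c(spk_n, idx)
        spk_t <- c(spk_t, tt[i] + frac * (tt[i + 1] - tt[i]))
      }
    }
  }
  new_spike_train(spk_n, spk_t, N, max(tt))
}

#' Map between membrane-potential and phase coordinates
#'
#' Applies the coordinate changes connecting the three model levels:
#' \eqn{v = \tan(\theta/2)} (QIF to theta) and
#' \eqn{2\tan(\theta/2) = \Omega\tan(\varphi/2)} (theta to the uniformly
#' rotating phase). The branch is kept consistent so that
#' \eqn{\theta = \pm\pi}, \eqn{\varphi = \pm\pi} and \eqn{v = \pm\infty}
#' correspond to each other; infinite voltages are accepted as
#' sentinels.
#'
#' @param values Vector of coordinates to transform.
#' @param direction One of `"v_to_theta"`, `"theta_to_v"`,
#'   `"theta_to_phi"`, `"phi_to_theta"`.
#' @param Omega Positive fast frequency, required for the phi maps.
#' @return Transformed vector.
#' @export
map_coordinates <- function(values,
                            direction = c("v_to_theta", "theta_to_v",
                                          "theta_to_phi", "phi_to_theta"),
                            Omega = NULL) {
  direction <- match.arg(direction)
  if (direction %in% c("theta_to_phi", "phi_to_theta")) {
    if (is.null(Omega) || length(Omega) != 1L || !is.finite(Omega) || Omega <= 0) {
      stop("`Omega` (positive scalar) is required for phi maps")
    }
  }
  switch(direction,
    v_to_theta = {
      out <- 2 * atan(values)
      out[is.infinite(values)] <- sign(values[is.infinite(values)]) * pi
      out
    },
    theta_to_v = tan(values / 2),
    theta_to_phi = half_angle_scale(values, 2 / Omega),
    phi_to_theta = half_angle_scale(values, Omega / 2)
  )
}

# phase -> 2 atan(scale * tan(phase/2)) on (-pi, pi]; +/- pi are fixed
# points of the map (tan(pi/2) overflows to a huge finite value whose
# arctangent is pi/2 to machine precision, so the limit is automatic)
half_angle_scale <- function(x, scale) {
  w <- wrap_angle(x)
  out <- 2 * atan(scale * tan(w / 2))
  out[abs(w) == pi] <- w[abs(w) == pi]
  out
}
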