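# Independent oracles used across the suite. These deliberately avoid
# the package's own closed forms and quadrature wrappers.

# Fourier coefficient of the transformed pulse by direct (complex)
# quadrature of its defining integral, written from the composition
# P_nu(2 atan((Omega/2) tan(phi/2))) without the package's log-space
# evaluator.
oracle_pulse_fourier <- function(ell, nu, Omega, parts = FALSE) {
  p_nu <- exp(nu * log(2) + 2 * lgamma(nu + 1) - log(pi) - lgamma(2 * nu + 1))
  qfun <- function(phi) {
    th <- 2 * atan(Omega * tan(phi / 2) / 2)
    p_nu * (1 - cos(th))^nu
  }
  brk <- pi - min(3, 10 / sqrt(nu))
  quad <- function(f) {
    stats::integrate(f, -pi, -brk, rel.tol = 1e-13, abs.tol = 1e-13,
                     subdivisions = 2000L)$value +
      stats::integrate(f, -brk, brk, rel.tol = 1e-13, abs.tol = 1e-13,
                       subdivisions = 2000L)$value +
      stats::integrate(f, brk, pi, rel.tol = 1e-13, abs.tol = 1e-13,
                       subdivisions = 2000L)$value
  }
  re <- quad(function(phi) cos(ell * phi) * qfun(phi)) / (2 * pi)
  im <- quad(function(phi) -sin(ell * phi) * qfun(phi)) / (2 * pi)
  if (parts) c(re = re, im = im) else re
}

# Kernel Fourier coefficient by quadrature in the time (not lag)
# variable, using stats::dgamma as the kernel: the gamma kernel equals
# the gamma density with shape q+1 and scale tau.
oracle_kernel_fourier <- function(ell, Omega, q, tau) {
  upper <- tau * ((q + 1) + 14 * sqrt(q + 1)) + 1
  re <- stats::integrate(function(t) stats::dgamma(t, q + 1, scale = tau) *
                           cos(ell * Omega * t),
                         0, upper, rel.tol = 1e-12, abs.tol = 1e-12,
                         subdivisions = 2000L)$value
  im <- stats::integrate(function(t) stats::dgamma(t, q + 1, scale = tau) *
                           sin(ell * Omega * t),
                         0, upper, rel.tol = 1e-12, abs.tol = 1e-12,
                         subdivisions = 2000L)$value
  complex(real = re, imaginary = -im)
}

# dense sign-scan of sin((q+1) atan(x)) used to count attractive
# intervals over the full axis
oracle_interval_count <- function(q, n = 400001L, xmax = 100) {
  x <- seq(-xmax, xmax, length.out = n)
  pos <- sin((q + 1) * atan(x)) > 0
  sum(diff(c(FALSE, pos)) == 1L)
}

run_settings <- function(dt = 0.01, T, keep_every = 10L) {
  integration_settings(dt = dt, T = T, keep_every = keep_every)
}
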