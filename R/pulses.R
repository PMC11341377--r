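#' Normalization constant of the finite-width pulse
#'
#' The pulse \eqn{P_\nu(\theta) = p_\nu (1 - \cos\theta)^\nu} is
#' normalized so that its circle integral equals 2, matching the weight
#' of the delta-comb limit \eqn{\nu \to \infty}. This fixes
#' \deqn{p_\nu = \frac{2^\nu (\nu!)^2}{\pi\,(2\nu)!},}
#' computed in log space.
#'
#' @param nu Positive integer pulse sharpness.
#' @return The scalar \eqn{p_\nu}.
#' @export
pulse_normalization <- function(nu) {
  check_nu(nu)
  exp(log_pulse_normalization(nu))
}

log_pulse_normalization <- function(nu) {
  nu * log(2) + 2 * lgamma(nu + 1) - log(pi) - lgamma(2 * nu + 1)
}

check_nu <- function(nu) {
  if (length(nu) != 1L || !is.finite(nu) || nu < 1 || nu != round(nu)) {
    stop("`nu` must be a single positive integer; use the delta-limit functions for nu = Inf")
  }
  invisible(nu)
}

#' Pulsatile synapse profile
#'
#' Evaluates \eqn{P_\nu(\theta) = p_\nu (1 - \cos\theta)^\nu}, the shape
#' of the pulsatile chemical synapse emitted as a neuron's phase
#' approaches the spike phase \eqn{\theta = \pi}. Larger `nu` gives a
#' sharper pulse; as \eqn{\nu \to \infty} the profile tends to a Dirac
#' comb of weight 2 centred at \eqn{\pi} (use the `delta`-limit code
#' paths for that case).
#'
#' @param theta Vector of phase angles (radians).
#' @param nu Positive integer sharpness.
#' @return Non-negative pulse values.
#' @export
pulse_value <- function(theta, nu) {
  check_nu(nu)
  # 1 - cos(theta) = 2 sin^2(theta/2); evaluate in log space
  s2 <- sin(theta / 2)^2
  out <- numeric(length(theta))
  pos <- s2 > 0
  out[pos] <- exp(log_pulse_normalization(nu) + nu * log(2 * s2[pos]))
  out
}

#' Pulse profile in the uniformly rotating phase
#'
#' Evaluates \eqn{Q_\nu(\varphi) = P_\nu(2\arctan(\tfrac{\Omega}{2}\tan\tfrac{\varphi}{2}))},
#' the pulse shape seen in the phase variable \eqn{\varphi} in which each
#' uncoupled neuron rotates uniformly at rate \eqn{\Omega}. The change of
#' variables \eqn{2\tan(\theta/2) = \Omega\tan(\varphi/2)} is the
#' identity when \eqn{\Omega = 2}; the endpoints \eqn{\varphi = \pm\pi}
#' map to \eqn{\theta = \pm\pi} in the limit.
#'
#' @param phi Vector of phase angles (radians).
#' @param nu Positive integer sharpness.
#' @param Omega Positive rotation frequency.
#' @return Non-negative pulse values, 2*pi-periodic and even in `phi`.
#' @export
transformed_pulse_value <- function(phi, nu, Omega) {
  check_nu(nu)
  stopifnot(length(Omega) == 1L, is.finite(Omega), Omega > 0)
  # 1 - cos(theta(phi)) = 2 Omega^2 s2 / (4 c2 + Omega^2 s2),
  # finite at phi = +/-pi where c2 = 0 (limit value 2).
  s2 <- sin(phi / 2)^2
  c2 <- cos(phi / 2)^2
  base <- 2 * Omega^2 * s2 / (4 * c2 + Omega^2 * s2)
  out <- numeric(length(phi))
  pos <- base > 0
  out[pos] <- exp(log_pulse_normalization(nu) + nu * log(base[pos]))
  out
}

#' Fourier coefficients of the transformed pulse
#'
#' Computes \eqn{Q_{\nu\ell} = \frac{1}{2\pi}\int_{-\pi}^{\pi}
#' e^{-i\ell\varphi} Q_\nu(\varphi)\, d\varphi}, which is real and even
#' in \eqn{\ell}. The `hypergeometric` method evaluates the closed form
#' \deqn{Q_{\nu\ell} = \frac{p_\nu 2^\nu}{\pi} \sum_{m=0}^{\ell}
#'   (-1)^m \binom{2\ell}{2m} \left(\frac{\Omega}{2}\right)^{2(\ell-m)+1}
#'   \frac{\Gamma(\nu+m+\frac12)\Gamma(\ell-m+\frac12)}{\Gamma(\nu+\ell+1)}
#'   \,{}_2F_1\!\left(\ell+1, \ell-m+\tfrac12; \nu+\ell+1;
#'   1-\tfrac{\Omega^2}{4}\right),}
#' which for \eqn{\ell = 0, 1} reduces to the elementary hypergeometric
#' expressions used in the reduction. When the hypergeometric argument
#' approaches unity (small `Omega`) the series converges too slowly and
#' the function falls back to adaptive quadrature of the defining
#' integral, with a message.
#'
#' @param ell Integer harmonic index (the coefficient is even in `ell`).
#' @param nu Positive integer sharpness.
#' @param Omega Positive rotation frequency.
#' @param method `"hypergeometric"` or `"quadrature"`.
#' @return A list of class `pulse_coefficient` with fields `ell`,
#'   `value` (real), and `method` actually used.
#' @seealso [delta_limit_coefficient()] for the \eqn{\nu = \infty} limit.
#' @export
pulse_fourier <- function(ell, nu, Omega,
                          method = c("hypergeometric", "quadrature")) {
  method <- match.arg(method)
  check_nu(nu)
  stopifnot(length(ell) == 1L, ell == round(ell))
  stopifnot(length(Omega) == 1L, is.finite(Omega), Omega > 0)
  ell <- abs(as.integer(ell)) # Q_{nu,-l} = Q_{nu,l}
  used <- method
  value <- if (method == "hypergeometric") {
    tryCatch(
      pulse_fourier_hyp(ell, nu, Omega),
      ksreduce_hyp2f1_error = function(e) {
        message(
          "hypergeometric evaluation of Q_nu,l did not converge (",
          conditionMessage(e), "); falling back to quadrature"
        )
        used <<- "quadrature"
        pulse_fourier_quad(ell, nu, Omega)
      }
    )
  } else {
    pulse_fourier_quad(ell, nu, Omega)
  }
  structure(list(ell = ell, value = value, method = used),
            class = "pulse_coefficient")
}

pulse_fourier_hyp <- function(ell, nu, Omega) {
  z <- 1 - Omega^2 / 4
  # direct series needs ~ 1/(1-z) terms; refuse near z = 1 so the
  # caller falls back to quadrature
  if (z > 0.95) {
    stop(hyp2f1_error("argument too close to 1 for the power series",
                      ell + 1, 0.5, nu + ell + 1, z))
  }
  s <- 0
  for (m in 0:ell) {
    lc <- log_pulse_normalization(nu) + nu * log(2) +
      lchoose(2 * ell, 2 * m) + (2 * (ell - m) + 1) * log(Omega / 2) +
      lgamma(nu + m + 0.5) + lgamma(ell - m + 0.5) -
      lgamma(nu + ell + 1) - log(pi)
    s <- s + (-1)^m * exp(lc) *
      hyp2f1(ell + 1, ell - m + 0.5, nu + ell + 1, z)
  }
  s
}

# Adaptive quadrature of the defining integral. The integrand
# concentrates near phi = pi with width ~ 1/sqrt(nu), so the domain is
# split there to keep the adaptive scheme honest at large nu.
pulse_fourier_quad <- function(ell, nu, Omega) {
  f <- function(phi) cos(ell * phi) * transformed_pulse_value(phi, nu, Omega)
  brk <- pi - min(3, 10 / sqrt(nu))
  i1 <- stats::integrate(f, 0, brk, rel.tol = 1e-13, abs.tol = 1e-13,
                         subdivisions = 2000L)
  i2 <- stats::integrate(f, brk, pi, rel.tol = 1e-13, abs.tol = 1e-13,
                         subdivisions = 2000L)
  if (i1$message != "OK" || i2$message != "OK") {
    stop(sprintf("pulse quadrature failed: %s / %s", i1$message, i2$message))
  }
  (i1$value + i2$value) / pi # evenness: integral over [-pi,pi] = 2x [0,pi]
}

#' Delta-pulse limit of the Fourier coefficients
#'
#' In the limit \eqn{\nu \to \infty} every coefficient converges to
#' \eqn{Q_{\infty\ell} = (-1)^\ell\, \Omega / (2\pi)}: the transformed
#' pulse becomes a Dirac comb of weight \eqn{\Omega} at
#' \eqn{\varphi = \pi}.
#'
#' @param ell Integer harmonic index.
#' @param Omega Positive rotation frequency.
#' @return A `pulse_coefficient` with the limit value.
#' @export
delta_limit_coefficient <- function(ell, Omega) {
  stopifnot(length(ell) == 1L, ell == round(ell))
  stopifnot(length(Omega) == 1L, is.finite(Omega), Omega > 0)
  structure(
    list(ell = as.integer(ell), value = (-1)^ell * Omega / (2 * pi),
         method = "delta_limit"),
    class = "pulse_coefficient"
  )
}

#' @export
print.pulse_coefficient <- function(x, ...) {
  cat(sprintf("<pulse_coefficient> ell = %d, value = %.8g (%s)\n",
              x$ell, x$value, x$method))
  invisible(x)
}
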