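#' Network parameter set
#'
#' Bundles the parameters of the globally coupled spiking network: the
#' excitability currents \eqn{\eta_n > 0} (all neurons in the
#' oscillatory regime, a requirement of the uniform-rotation change of
#' variables), the common synaptic weight \eqn{\varkappa}, the pulse
#' sharpness \eqn{\nu} (a positive integer, or `Inf` for delta pulses),
#' and the synaptic kernel.
#'
#' @param eta Vector of N positive excitability currents.
#' @param kappa Synaptic coupling weight (negative = inhibitory, which
#'   for delta-like pulses is the attractive sign).
#' @param nu Positive integer pulse sharpness, or `Inf`.
#' @param kernel A [synaptic_kernel()].
#' @return An object of class `network_params`.
#' @export
network_params <- function(eta, kappa, nu, kernel) {
  if (length(eta) < 2L) stop("need at least N = 2 neurons")
  if (any(!is.finite(eta)) || any(eta <= 0)) {
    stop("all `eta` must be positive (oscillatory regime)")
  }
  stopifnot(length(kappa) == 1L, is.finite(kappa))
  if (!(identical(nu, Inf) || (length(nu) == 1L && is.finite(nu) &&
                               nu >= 1 && nu == round(nu)))) {
    stop("`nu` must be a positive integer or Inf")
  }
  if (!inherits(kernel, "synaptic_kernel")) stop("`kernel` must be a synaptic_kernel")
  structure(
    list(N = length(eta), eta = as.numeric(eta), kappa = as.numeric(kappa),
         nu = nu, kernel = kernel),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "<network_params> N = %d, mean(eta) = %g, kappa = %g, nu = %s\n",
    x$N, mean(x$eta), x$kappa, if (is.infinite(x$nu)) "Inf (delta pulses)" else x$nu
  ))
  print(x$kernel)
  invisible(x)
}

# Q_nu0 as a function of Omega, dispatching on finite/infinite nu
q_nu0 <- function(nu, Omega) {
  if (is.infinite(nu)) Omega / (2 * pi) else pulse_fourier(0L, nu, Omega)$value
}

q_nu1 <- function(nu, Omega) {
  if (is.infinite(nu)) -Omega / (2 * pi) else pulse_fourier(1L, nu, Omega)$value
}

#' Self-consistent fast rotation frequency
#'
#' Solves the nonlinear scalar equation
#' \deqn{\langle\eta\rangle - \Omega^2/4 + \varkappa\, Q_{\nu 0}(\Omega) = 0}
#' for the fast rotation frequency \eqn{\Omega > 0}, chosen so that the
#' reduced natural frequencies have zero mean. For delta pulses
#' (\eqn{\nu = \infty}, \eqn{Q_{\infty 0} = \Omega/2\pi}) the equation is
#' quadratic with the closed-form root
#' \eqn{\Omega = (\varkappa + \sqrt{\varkappa^2 +
#' 4\pi^2\langle\eta\rangle})/\pi}.
#'
#' If several roots exist in the search bracket, the one closest to the
#' uncoupled value \eqn{2\sqrt{\langle\eta\rangle}} is returned.
#'
#' @param eta_mean Positive mean excitability current.
#' @param kappa Synaptic coupling weight.
#' @param nu Positive integer pulse sharpness, or `Inf`.
#' @param tol Root-finder tolerance.
#' @return The positive root `Omega`.
#' @examples
#' solve_omega(2, -0.2 * pi, 20) # approx 2.639
#' solve_omega(2, 0, 20)         # exactly 2 sqrt(2)
#' @export
solve_omega <- function(eta_mean, kappa, nu, tol = 1e-12) {
  stopifnot(length(eta_mean) == 1L, is.finite(eta_mean))
  if (eta_mean <= 0) stop("`eta_mean` must be positive")
  stopifnot(length(kappa) == 1L, is.finite(kappa))
  if (is.infinite(nu)) {
    return((kappa + sqrt(kappa^2 + 4 * pi^2 * eta_mean)) / pi)
  }
  check_nu(nu)
  # the bracket scan touches tiny Omega where the hypergeometric path
  # predictably defers to quadrature; no need to log each fallback
  f <- function(Om) eta_mean - Om^2 / 4 + kappa * suppressMessages(q_nu0(nu, Om))
  lo <- 1e-6
  hi <- 2 * sqrt(eta_mean) + 2 * abs(kappa) + 1
  grid <- seq(lo, hi, length.out = 61L)
  fg <- vapply(grid, f, numeric(1))
  sc <- which(fg[-1] * fg[-length(fg)] <= 0)
  if (length(sc) == 0L) {
    stop(sprintf(
      paste0("no sign change of the frequency equation on [%g, %g] ",
             "(f(lo) = %g, f(hi) = %g)"),
      lo, hi, fg[1], fg[length(fg)]
    ))
  }
  roots <- vapply(sc, function(i) {
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = tol)$root
  }, numeric(1))
  roots[which.min(abs(roots - 2 * sqrt(eta_mean)))]
}

#' Reduce a spiking network to the Kuramoto-Sakaguchi model
#'
#' Computes the parameters of the phase model
#' \deqn{\dot\phi_n = \omega_n + \frac{K}{N}\sum_{n'}
#'   \sin(\phi_{n'} - \phi_n - \alpha)}
#' that approximates the slow phase drifts of the weakly coupled
#' QIF/theta network:
#' \deqn{\omega_n = \frac{2(\eta_n - \Omega^2/4 + \varkappa Q_{\nu 0})}{\Omega},
#' \quad K = \frac{2\varkappa |G_1| Q_{\nu 1}}{\Omega},
#' \quad \alpha = -\arg G_1 - \frac{\pi}{2},}
#' with \eqn{\Omega} from [solve_omega()], the pulse coefficients
#' \eqn{Q_{\nu 0}, Q_{\nu 1}} from [pulse_fourier()] (or their delta
#' limits \eqn{\pm\Omega/2\pi}), and the kernel coefficient \eqn{G_1}
#' from [kernel_fourier()]. `alpha` is wrapped to \eqn{(-\pi, \pi]}.
#' Since \eqn{Q_{\nu 1} \le 0}, `K` and `kappa` always have opposite
#' signs for \eqn{\Omega > 0}.
#'
#' @param params A [network_params()] object.
#' @return An object of class `ks_params` with fields `omega` (length-N,
#'   zero mean by construction), `K`, `alpha`, `Omega`, plus the
#'   intermediate quantities `Q0`, `Q1`, `G1` and the originating
#'   `params`.
#' @export
reduce_to_ks <- function(params) {
  stopifnot(inherits(params, "network_params"))
  Omega <- solve_omega(mean(params$eta), params$kappa, params$nu)
  Q0 <- q_nu0(params$nu, Omega)
  Q1 <- q_nu1(params$nu, Omega)
  method <- if (is_gamma_kernel(params$kernel)) "closed_form" else "quadrature"
  G1 <- kernel_fourier(1L, Omega, params$kernel, method = method)$value
  omega <- 2 * (params$eta - Omega^2 / 4 + params$kappa * Q0) / Omega
  K <- 2 * params$kappa * Mod(G1) * Q1 / Omega
  alpha <- wrap_angle(-Arg(G1) - pi / 2)
  structure(
    list(omega = omega, K = K, alpha = alpha, Omega = Omega,
         Q0 = Q0, Q1 = Q1, G1 = G1, params = params),
    class = "ks_params"
  )
}

#' @export
print.ks_params <- function(x, ...) {
  cat(sprintf(
    paste0("<ks_params> N = %d\n  Omega = %.6g, K = %.6g, alpha = %.6g rad\n",
           "  K cos(alpha) = %.6g (%s coupling)\n",
           "  omega: mean %.3g, sd %.3g\n"),
    length(x$omega), x$Omega, x$K, x$alpha, x$K * cos(x$alpha),
    if (x$K * cos(x$alpha) > 0) "attractive" else "repulsive",
    mean(x$omega), stats::sd(x$omega)
  ))
  invisible(x)
}

#' Wrap angles to the principal interval
#'
#' Maps angles (radians) to \eqn{(-\pi, \pi]}.
#'
#' @param x Numeric vector, matrix or array of angles.
#' @return Wrapped angles with the shape of `x`.
#' @export
wrap_angle <- function(x) {
  out <- atan2(sin(x), cos(x))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Is the effective phase coupling attractive?
#'
#' The reduced coupling is attractive when \eqn{K\cos\alpha > 0}. For a
#' gamma kernel of order `q`, \eqn{\alpha = (q+1)\arctan(\tau\Omega) -
#' \pi/2} and \eqn{\mathrm{sign}(K) = -\mathrm{sign}(\varkappa)}, so for
#' inhibitory coupling (\eqn{\varkappa < 0}) attractiveness reduces to
#' \eqn{\sin((q+1)\arctan(\tau\Omega)) > 0}.
#'
#' @param q Non-negative integer kernel order.
#' @param tau Positive synaptic time constant.
#' @param Omega Positive fast frequency (from [solve_omega()]).
#' @param kappa Synaptic coupling weight (sign matters).
#' @return `TRUE` for attractive, `FALSE` for repulsive coupling.
#' @export
is_attractive <- function(q, tau, Omega, kappa) {
  stopifnot(length(q) == 1L, q >= 0, q == round(q))
  stopifnot(length(tau) == 1L, tau > 0, length(Omega) == 1L, Omega > 0)
  stopifnot(length(kappa) == 1L, is.finite(kappa), kappa != 0)
  G1 <- (1 + 1i * Omega * tau)^(-(q + 1))
  alpha <- wrap_angle(-Arg(G1) - pi / 2)
  sign_K <- -sign(kappa) # Q_nu1 <= 0 and Omega > 0
  unname(sign_K * cos(alpha) > 0)
}

#' Intervals of attractive coupling in the delay-frequency product
#'
#' For inhibitory coupling and a gamma kernel of order `q`, the coupling
#' is attractive exactly where \eqn{\sin((q+1)\arctan(x)) > 0} with
#' \eqn{x = \tau\Omega}. The maximal such intervals have endpoints at
#' \eqn{x = \tan(k\pi/(q+1))}. Over the physical half-axis
#' \eqn{x > 0} the first interval is \eqn{(0, \tan(\pi/(q+1)))}
#' (unbounded for `q = 0`); over the full axis the total number of
#' intervals is \eqn{\lfloor q/2\rfloor + 1}.
#'
#' @param q Non-negative integer kernel order.
#' @param domain `"positive"` (default, x > 0) or `"full"` (both signs).
#' @return A two-column matrix of interval endpoints (`lower`, `upper`),
#'   possibly infinite, ordered by `lower`.
#' @export
attractive_intervals <- function(q, domain = c("positive", "full")) {
  stopifnot(length(q) == 1L, q >= 0, q == round(q))
  domain <- match.arg(domain)
  p <- q + 1
  ivals <- list()
  # positive side: arctan(x) in (2k pi/p, (2k+1) pi/p) intersect (0, pi/2)
  k <- 0
  while (2 * k * pi / p < pi / 2) {
    lo_y <- 2 * k * pi / p
    hi_y <- (2 * k + 1) * pi / p
    lo <- if (k == 0) 0 else tan(lo_y)
    hi <- if (hi_y >= pi / 2) Inf else tan(hi_y)
    ivals[[length(ivals) + 1L]] <- c(lo, hi)
    k <- k + 1
  }
  if (domain == "full") {
    # negative side: arctan(x) in (-(2j+2) pi/p, -(2j+1) pi/p) intersect (-pi/2, 0)
    j <- 0
    while ((2 * j + 1) * pi / p < pi / 2) {
      hi_y <- -(2 * j + 1) * pi / p
      lo_y <- -(2 * j + 2) * pi / p
      hi <- tan(hi_y)
      lo <- if (lo_y <= -pi / 2) -Inf else tan(lo_y)
      ivals[[length(ivals) + 1L]] <- c(lo, hi)
      j <- j + 1
    }
  }
  m <- do.call(rbind, ivals)
  colnames(m) <- c("lower", "upper")
  m[order(m[, "lower"]), , drop = FALSE]
}

#' Map of attractive and repulsive coupling regions
#'
#' Sweeps a grid of synaptic time constants and common excitability
#' currents, solving the frequency equation once per `eta` (it does not
#' involve `tau`) and applying [is_attractive()] in each cell.
#'
#' @param q Non-negative integer kernel order.
#' @param kappa Synaptic coupling weight.
#' @param nu Positive integer pulse sharpness or `Inf`.
#' @param tau_grid Positive vector of synaptic time constants.
#' @param eta_grid Positive vector of common excitability currents.
#' @return An object of class `coupling_region_map`: a list with
#'   `tau_grid`, `eta_grid`, `q`, `kappa`, `nu`, `Omega` (per eta), and
#'   the logical matrix `attractive` (rows = tau, cols = eta; `NA` where
#'   the frequency equation failed).
#' @export
region_map <- function(q, kappa, nu, tau_grid, eta_grid) {
  stopifnot(length(tau_grid) >= 1L, all(tau_grid > 0))
  stopifnot(length(eta_grid) >= 1L, all(eta_grid > 0))
  Omegas <- vapply(eta_grid, function(eta) {
    tryCatch(solve_omega(eta, kappa, nu), error = function(e) {
      warning(sprintf("eta = %g: %s", eta, conditionMessage(e)))
      NA_real_
    })
  }, numeric(1))
  att <- matrix(NA, nrow = length(tau_grid), ncol = length(eta_grid),
                dimnames = list(NULL, NULL))
  for (j in seq_along(eta_grid)) {
    if (is.na(Omegas[j])) next
    att[, j] <- vapply(tau_grid, is_attractive, logical(1),
                       q = q, Omega = Omegas[j], kappa = kappa)
  }
  structure(
    list(tau_grid = as.numeric(tau_grid), eta_grid = as.numeric(eta_grid),
         q = as.integer(q), kappa = kappa, nu = nu, Omega = Omegas,
         attractive = att),
    class = "coupling_region_map"
  )
}

#' @export
print.coupling_region_map <- function(x, ...) {
  cat(sprintf(
    "<coupling_region_map> q = %d, kappa = %g, nu = %s; %d x %d cells (%.1f%% attractive)\n",
    x$q, x$kappa, if (is.infinite(x$nu)) "Inf" else x$nu,
    length(x$tau_grid), length(x$eta_grid),
    100 * mean(x$attractive, na.rm = TRUE)
  ))
  invisible(x)
}
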