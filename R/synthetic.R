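# Seeded generators for initial conditions and excitability currents.
# These define the study conditions of the bundled scenarios; all
# randomness flows through the seed argument so every run is exactly
# reproducible.

#' Generate initial phases
#'
#' Three modes: `uniform` draws phases independently from
#' \eqn{[-\pi, \pi]}; `near_sync` places all oscillators at phase 0;
#' `near_cyclops` (odd `N = 2m + 1` only) places two m-oscillator
#' clusters at \eqn{\pm\arccos(-1/2m)} and one solitary oscillator at 0
#' — the three-cluster configuration with exactly vanishing first-order
#' order parameter. The deterministic modes add an independent uniform
#' perturbation of half-width `perturbation` to every phase.
#'
#' @param N Number of oscillators (>= 2; odd for `near_cyclops`).
#' @param mode `"uniform"`, `"near_cyclops"` or `"near_sync"`.
#' @param seed Integer seed; the result is a pure function of the
#'   arguments.
#' @param perturbation Non-negative half-width (radians) of the uniform
#'   perturbation applied in the deterministic modes.
#' @return Vector of N phases in \eqn{(-\pi, \pi]}.
#' @export
make_initial_phases <- function(N, mode = c("uniform", "near_cyclops", "near_sync"),
                                seed = 1L, perturbation = 0.01) {
  mode <- match.arg(mode)
  stopifnot(length(N) == 1L, N >= 2, N == round(N))
  stopifnot(perturbation >= 0)
  with_seed(seed, {
    base <- switch(mode,
      uniform = stats::runif(N, -pi, pi),
      near_sync = numeric(N),
      near_cyclops = {
        if (N %% 2 == 0) stop("`near_cyclops` requires odd N = 2m + 1")
        m <- (N - 1) / 2
        a <- acos(-1 / (2 * m)) # r1 = 0 for clusters (m, m) at +/-a plus one at 0
        c(rep(a, m), rep(-a, m), 0)
      }
    )
    if (mode != "uniform" && perturbation > 0) {
      base <- base + stats::runif(N, -perturbation, perturbation)
    }
    wrap_angle(base)
  })
}

#' Generate heterogeneous excitability currents
#'
#' Draws N currents uniformly from
#' \eqn{[\bar\eta - \delta\eta/2,\ \bar\eta + \delta\eta/2]}. With
#' `delta_eta = 0` the constant vector is returned (no draw consumed).
#'
#' @param N Number of neurons.
#' @param eta_mean Mean current (must leave the support positive).
#' @param delta_eta Non-negative spread.
#' @param seed Integer seed.
#' @return Vector of N positive currents.
#' @export
make_eta <- function(N, eta_mean, delta_eta = 0, seed = 1L) {
  stopifnot(length(N) == 1L, N >= 1, N == round(N))
  stopifnot(delta_eta >= 0)
  if (eta_mean - delta_eta / 2 <= 0) {
    stop("support of eta must be positive: eta_mean - delta_eta/2 > 0")
  }
  if (delta_eta == 0) return(rep(eta_mean, N))
  with_seed(seed, stats::runif(N, eta_mean - delta_eta / 2, eta_mean + delta_eta / 2))
}

# run code under a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
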