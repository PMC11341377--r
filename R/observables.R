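#' Kuramoto order parameters
#'
#' Computes the complex order parameters
#' \eqn{R_\ell(t) = \frac1N \sum_{n'} e^{i\ell\varphi_{n'}(t)}} for
#' \eqn{\ell = 1, 2} (or any requested harmonics). The modulus
#' \eqn{r_1} measures phase synchrony (1 = full synchrony), while
#' \eqn{r_2} measures two-cluster coherence; \eqn{r_1 \approx 0} with
#' the phases spread out marks a generalized splay state.
#'
#' @param x A `trajectory` object or an N x T matrix of phases (rows =
#'   oscillators).
#' @param ell Integer vector of harmonics (default `c(1, 2)`).
#' @return A data frame of class `order_parameter_series` with columns
#'   `time` and, for each harmonic, `r<ell>` (modulus) and `psi<ell>`
#'   (argument).
#' @export
order_parameters <- function(x, ell = c(1L, 2L)) {
  if (inherits(x, "trajectory")) {
    phases <- x$states
    times <- x$times
  } else {
    phases <- as.matrix(x)
    times <- seq_len(ncol(phases)) - 1
  }
  stopifnot(all(ell == round(ell)), all(is.finite(phases)))
  out <- data.frame(time = times)
  for (l in ell) {
    Z <- colMeans(exp(1i * l * phases))
    out[[paste0("r", l)]] <- Mod(Z)
    out[[paste0("psi", l)]] <- Arg(Z)
  }
  class(out) <- c("order_parameter_series", "data.frame")
  out
}

#' Population firing rate in a sliding window
#'
#' Computes \eqn{\rho(t) = \frac{1}{N\,\Delta t}\,\#\{\text{spikes in }
#' (t - \Delta t,\, t]\}}, the average rate at which neurons emit
#' spikes.
#'
#' @param spikes A spike train from the simulators or [detect_spikes()].
#' @param window Positive window width \eqn{\Delta t}.
#' @param times Vector of evaluation times.
#' @param N Number of neurons; taken from the spike train attribute if
#'   available.
#' @return Vector of rates, one per evaluation time.
#' @export
firing_rate <- function(spikes, window, times, N = attr(spikes, "N")) {
  if (is.null(N)) stop("`N` must be supplied when the spike train lacks it")
  stopifnot(length(window) == 1L, window > 0)
  st <- sort(spikes$time)
  if (length(st) == 0L) return(numeric(length(times)))
  upper <- findInterval(times, st)
  lower <- findInterval(times - window, st)
  (upper - lower) / (N * window)
}

#' Partition phases into circular clusters
#'
#' Single-linkage clustering on the circle: oscillators closer than
#' `tolerance` (circular distance) to a neighbour belong to the same
#' cluster. Returns the cluster sizes in decreasing order.
#'
#' @param phases Vector of phases (radians).
#' @param tolerance Positive linking distance in radians.
#' @return Integer vector of cluster sizes, decreasing, summing to
#'   `length(phases)`.
#' @export
detect_clusters <- function(phases, tolerance = 0.05) {
  stopifnot(length(tolerance) == 1L, tolerance > 0)
  n <- length(phases)
  if (n == 0L) return(integer(0))
  ph <- sort(wrap_angle(phases))
  gaps <- diff(ph)
  brk <- which(gaps > tolerance)
  if (length(brk) == 0L) return(n) # single cluster (possibly whole circle)
  sizes <- diff(c(0L, brk, n))
  # the circle closes: merge the first and last arcs if adjacent
  wrap_gap <- ph[1] + 2 * pi - ph[n]
  if (length(sizes) > 1L && wrap_gap <= tolerance) {
    sizes[1] <- sizes[1] + sizes[length(sizes)]
    sizes <- sizes[-length(sizes)]
  }
  sort(as.integer(sizes), decreasing = TRUE)
}

#' Classify the long-time dynamical regime
#'
#' Evaluates the post-transient window of a trajectory in a common phase
#' coordinate and assigns one of four labels: `synchronized` when the
#' time-mean first-order parameter exceeds `sync_threshold`; `cyclops`
#' when the cluster pattern (m, m, 1) — two equal coherent clusters plus
#' a solitary oscillator — persists on at least `persistence` of the
#' samples; `generalized_splay` when the time-mean \eqn{r_1} is below
#' `splay_threshold`; otherwise `other`.
#'
#' Theta-model trajectories are mapped to the uniformly rotating phase
#' (requires `Omega`) so that all three model levels are classified in
#' the same coordinate; Kuramoto-Sakaguchi slow phases differ from it
#' only by the global rotation \eqn{\Omega t}, which leaves moduli and
#' cluster structure unchanged.
#'
#' @param trajectory A `trajectory` object.
#' @param Omega Fast frequency for the theta-to-phi map (defaults to the
#'   trajectory's own, if recorded).
#' @param transient_frac Fraction of the horizon discarded as transient.
#' @param sync_threshold,splay_threshold Thresholds on the time-mean
#'   \eqn{r_1}.
#' @param cluster_tol Circular linking distance for [detect_clusters()].
#' @param persistence Minimum fraction of post-transient samples showing
#'   the cyclops pattern.
#' @return An object of class `regime_report` with the label, modal
#'   cluster sizes, long-time means of \eqn{r_1, r_2} and the settings
#'   used.
#' @export
classify_regime <- function(trajectory, Omega = trajectory$Omega,
                            transient_frac = 0.5,
                            sync_threshold = 0.95, splay_threshold = 0.1,
                            cluster_tol = 0.05, persistence = 0.9) {
  stopifnot(inherits(trajectory, "trajectory"))
  stopifnot(transient_frac >= 0, transient_frac < 1)
  phases <- trajectory$states
  if (trajectory$model_tag == "theta") {
    if (is.null(Omega)) {
      stop("`Omega` is required to classify theta-model trajectories in the common coordinate")
    }
    phases <- half_angle_scale(phases, 2 / Omega)
  }
  tt <- trajectory$times
  keep <- tt >= (min(tt) + transient_frac * (max(tt) - min(tt)))
  if (sum(keep) < 2L) stop("trajectory shorter than twice the transient window")
  phases <- phases[, keep, drop = FALSE]
  Z1 <- colMeans(exp(1i * phases))
  Z2 <- colMeans(exp(2i * phases))
  r1_mean <- mean(Mod(Z1))
  r2_mean <- mean(Mod(Z2))
  sizes_list <- lapply(seq_len(ncol(phases)),
                       function(i) detect_clusters(phases[, i], cluster_tol))
  key <- vapply(sizes_list, paste, character(1), collapse = ",")
  modal <- sizes_list[[which.max(ave(seq_along(key), key, FUN = length))]]
  is_cyclops <- vapply(sizes_list, function(sz) {
    length(sz) == 3L && sz[3] == 1L && sz[1] == sz[2] && sz[1] > 1L
  }, logical(1))
  label <- if (r1_mean > sync_threshold) {
    "synchronized"
  } else if (mean(is_cyclops) >= persistence) {
    "cyclops"
  } else if (r1_mean < splay_threshold) {
    "generalized_splay"
  } else {
    "other"
  }
  structure(
    list(label = label,
         cluster_sizes = modal,
         r1_longtime_mean = r1_mean,
         r2_longtime_mean = r2_mean,
         cyclops_fraction = mean(is_cyclops),
         settings = list(transient_frac = transient_frac,
                         sync_threshold = sync_threshold,
                         splay_threshold = splay_threshold,
                         cluster_tol = cluster_tol,
                         persistence = persistence)),
    class = "regime_report"
  )
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf(
    "<regime_report> %s\n  clusters: [%s], r1 = %.4f, r2 = %.4f (post-transient means)\n",
    x$label, paste(x$cluster_sizes, collapse = ", "),
    x$r1_longtime_mean, x$r2_longtime_mean
  ))
  invisible(x)
}
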