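# Gauss hypergeometric 2F1 for the pulse-coefficient closed forms.
#
# All uses in this package have small positive a, b, a large third
# parameter c, and real argument z = 1 - Omega^2/4 < 1.  The power
# series converges geometrically for |z| < 1; negative arguments are
# mapped into (0, 1) with the Pfaff transformation
#   2F1(a, b; c; z) = (1 - z)^(-a) 2F1(a, c - b; c; z / (z - 1)).
# Arguments close to +1 (Omega near 0) converge too slowly and raise a
# condition that callers catch to fall back to quadrature.

hyp2f1 <- function(a, b, c, z, tol = 1e-15, maxit = 10000L) {
  stopifnot(is.finite(z))
  if (z >= 1) {
    stop(hyp2f1_error("hypergeometric argument >= 1", a, b, c, z))
  }
  if (z < 0) {
    return((1 - z)^(-a) * hyp2f1(a, c - b, c, z / (z - 1), tol, maxit))
  }
  term <- 1
  s <- 1
  for (k in seq_len(maxit) - 1) {
    term <- term * (a + k) * (b + k) / ((c + k) * (1 + k)) * z
    s <- s + term
    if (abs(term) <= tol * abs(s)) {
      return(s)
    }
  }
  stop(hyp2f1_error(
    sprintf("hypergeometric series did not converge in %d terms", maxit),
    a, b, c, z
  ))
}

hyp2f1_error <- function(msg, a, b, c, z) {
  structure(
    class = c("ksreduce_hyp2f1_error", "error", "condition"),
    list(
      message = sprintf("%s (a=%g, b=%g, c=%g, z=%g)", msg, a, b, c, z),
      call = sys.call(-1)
    )
  )
}
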