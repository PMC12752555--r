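# Independent oracles used to freeze expected values: plain bisection on the
# Marko-Siggia force law, closed-form Evans-Ritchie survival, and quadrature
# moments.  These deliberately do not share code with the package internals.

bisect_wlc <- function(force, contour, lp, kbt = 4.1, tol = 1e-12) {
  ms <- function(z) (kbt / lp) * (0.25 / (1 - z / contour)^2 - 0.25 +
                                    z / contour)
  lo <- 0; hi <- contour * (1 - 1e-12)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ms(mid) < force) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

er_cdf_oracle <- function(f, k0, x, r, kbt = 4.1, f0 = 0) {
  c0 <- k0 * kbt / (x * r)
  1 - exp(c0 * (exp(x * f0 / kbt) - exp(x * f / kbt)))
}

er_mean_oracle <- function(k0, x, r, kbt = 4.1) {
  # E[F] = integral of the survival function
  stats::integrate(function(f) 1 - er_cdf_oracle(f, k0, x, r, kbt),
                   0, 500, rel.tol = 1e-10)$value
}

er_sd_oracle <- function(k0, x, r, kbt = 4.1) {
  m <- er_mean_oracle(k0, x, r, kbt)
  m2 <- stats::integrate(function(f) 2 * f *
                           (1 - er_cdf_oracle(f, k0, x, r, kbt)),
                         0, 500, rel.tol = 1e-10)$value
  sqrt(m2 - m^2)
}

ks_distance <- function(samples, cdf) {
  s <- sort(samples)
  n <- length(s)
  p <- cdf(s)
  max(abs(p - seq_len(n) / n), abs(p - (seq_len(n) - 1) / n))
}
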