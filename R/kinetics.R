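# Force-dependent rate laws (Bell model), the rupture-force distribution at
# constant loading rate (Evans-Ritchie), their fitting, and derived
# thermodynamic quantities.

#' Bell-model rate parameters
#'
#' A zero-force rate constant and a transition distance, with the sign
#' convention that unfolding rates increase with force (`sign = +1`) and
#' folding rates decrease (`sign = -1`).
#'
#' @param k0 Zero-force rate constant, 1/s (> 0).
#' @param x Transition distance, nm (> 0).
#' @param sign Either `"unfolding"`/`+1` or `"folding"`/`-1`.
#' @param k0_err,x_err Optional standard errors.
#' @param n_events Optional number of events behind a fitted value.
#' @return An object of class `bell_params`.
#' @examples
#' bp <- bell_params(2.4e-2, 0.7)
#' bell_rate(11.5, bp)
#' @export
bell_params <- function(k0, x, sign = c("unfolding", "folding"),
                        k0_err = NA_real_, x_err = NA_real_,
                        n_events = NA_integer_) {
  check_scalar_positive(k0, "k0")
  check_scalar_positive(x, "x")
  if (is.numeric(sign)) {
    if (!sign %in% c(1, -1)) stop_invalid("numeric `sign` must be +1 or -1")
    s <- as.integer(sign)
  } else {
    s <- switch(match.arg(sign), unfolding = 1L, folding = -1L)
  }
  structure(list(k0 = k0, x = x, sign = s,
                 k0_err = k0_err, x_err = x_err,
                 n_events = n_events),
            class = "bell_params")
}

#' @export
print.bell_params <- function(x, ...) {
  lab <- if (x$sign > 0) "unfolding" else "folding"
  cat(sprintf("Bell parameters (%s): k0 = %.4g 1/s", lab, x$k0))
  if (is.finite(x$k0_err)) cat(sprintf(" (+/- %.2g)", x$k0_err))
  cat(sprintf(", x = %.3g nm", x$x))
  if (is.finite(x$x_err)) cat(sprintf(" (+/- %.2g)", x$x_err))
  cat("\n")
  invisible(x)
}

#' Bell-model force-dependent rate
#'
#' k(f) = k0 * exp(sign * f * x / k_BT), evaluated in log space to avoid
#' overflow at extreme arguments.
#'
#' @param force Force, pN (vectorized, >= 0).
#' @param params A [bell_params()] object.
#' @param thermal_energy k_BT, pN nm.
#' @return Rate in 1/s.
#' @export
bell_rate <- function(force, params, thermal_energy = 4.1) {
  stopifnot(inherits(params, "bell_params"))
  check_nonnegative_force(force)
  exp(log(params$k0) + params$sign * force * params$x / thermal_energy)
}

#' Evans-Ritchie rupture-force density at constant loading rate
#'
#' Probability density of the force at which a Bell-model transition first
#' fires while the force grows linearly at rate r from 0:
#' p(F) = (k(F)/r) * exp\[(k0 k_BT)/(x r) * (1 - exp(F x / k_BT))\].
#'
#' @param rupture_force Force, pN (vectorized).
#' @param params A [bell_params()] object (unfolding sign).
#' @param loading_rate Loading rate r, pN/s (> 0).
#' @param thermal_energy k_BT, pN nm.
#' @return Density in 1/pN.
#' @export
evans_ritchie_pdf <- function(rupture_force, params, loading_rate,
                              thermal_energy = 4.1) {
  stopifnot(inherits(params, "bell_params"))
  check_scalar_positive(loading_rate, "loading_rate")
  a <- params$x / thermal_energy
  c0 <- params$k0 * thermal_energy / (params$x * loading_rate)
  logp <- log(params$k0 / loading_rate) + a * rupture_force +
    c0 * (1 - exp(a * rupture_force))
  out <- exp(logp)
  out[rupture_force < 0] <- 0
  out
}

# Survival function of the Evans-Ritchie process starting at force f0.
evans_ritchie_survival <- function(force, params, loading_rate,
                                   thermal_energy = 4.1, f0 = 0) {
  a <- params$x / thermal_energy
  c0 <- params$k0 * thermal_energy / (params$x * loading_rate)
  exp(c0 * (exp(a * f0) - exp(a * force)))
}

#' Most probable rupture force at constant loading rate
#'
#' Closed-form mode of the Evans-Ritchie density,
#' F* = (k_BT/x) * log(x r / (k0 k_BT)), clamped at 0 when the argument of
#' the logarithm does not exceed 1 (barrierless immediate rupture).
#'
#' @inheritParams evans_ritchie_pdf
#' @return Force in pN.
#' @examples
#' most_probable_force(bell_params(2.4e-2, 0.7), 1) # ~ 11.5 pN
#' @export
most_probable_force <- function(params, loading_rate, thermal_energy = 4.1) {
  stopifnot(inherits(params, "bell_params"))
  check_scalar_positive(loading_rate, "loading_rate")
  arg <- params$x * loading_rate / (params$k0 * thermal_energy)
  if (arg <= 1) return(0)
  (thermal_energy / params$x) * log(arg)
}

#' Sample rupture forces from the Evans-Ritchie distribution
#'
#' Inverse-CDF sampling from the survival function
#' S(F) = exp\[(k0 k_BT)/(x r) (1 - exp(F x / k_BT))\]; deterministic for a
#' given seed, and leaves the caller's RNG stream untouched.
#'
#' @param n Number of forces to draw (>= 1).
#' @param params A [bell_params()] object.
#' @param loading_rate Loading rate, pN/s.
#' @param thermal_energy k_BT, pN nm.
#' @param seed Integer seed (required for reproducibility; `NULL` uses the
#'   current RNG stream).
#' @return Numeric vector of forces, pN.
#' @export
sample_rupture_forces <- function(n, params, loading_rate,
                                  thermal_energy = 4.1, seed = NULL) {
  stopifnot(inherits(params, "bell_params"), n >= 1)
  check_scalar_positive(loading_rate, "loading_rate")
  with_seed(seed, {
    u <- stats::runif(n)
    rupture_quantile(u, params, loading_rate, thermal_energy)
  })
}

# Quantile function: solves S(F) = 1 - p in closed form.
rupture_quantile <- function(p, params, loading_rate, thermal_energy = 4.1) {
  a <- params$x / thermal_energy
  c0 <- params$k0 * thermal_energy / (params$x * loading_rate)
  # S(F) = exp(c0 (1 - e^{aF})) = 1 - p  =>  e^{aF} = 1 - log(1-p)/c0
  log1p(-log1p(-p) / c0) / a
}

#' Fit the Bell model to force-resolved rate estimates
#'
#' Weighted least squares of log(rate) against force. Weights are derived
#' from the rate standard errors by the delta method
#' (var\[log k\] = (se/k)^2); when no errors are supplied the fit is
#' unweighted. The slope sign determines the branch (unfolding/folding) and
#' the transition distance is always reported positive.
#'
#' @param rates A data frame with columns `force` (pN), `rate` (1/s) and
#'   optionally `stderr` (1/s) and `n_events` (see [rate_estimate()]).
#' @param thermal_energy k_BT, pN nm.
#' @return A [bell_params()] object carrying `k0_err` and `x_err` from the
#'   covariance of the linear fit.
#' @export
fit_bell <- function(rates, thermal_energy = 4.1) {
  stopifnot(is.data.frame(rates), all(c("force", "rate") %in% names(rates)))
  rates <- rates[is.finite(rates$rate) & rates$rate > 0, , drop = FALSE]
  if (nrow(rates) < 3 || length(unique(rates$force)) < 3) {
    stop_invalid("fit_bell needs rate estimates at >= 3 distinct forces")
  }
  w <- NULL
  if (!is.null(rates$stderr) && all(is.finite(rates$stderr)) &&
      all(rates$stderr > 0)) {
    w <- (rates$rate / rates$stderr)^2
  }
  fit <- stats::lm(log(rate) ~ force, data = rates, weights = w)
  co <- stats::coef(fit)
  # noiseless synthetic rates make the fit exact; the perfect-fit warning
  # from summary.lm is expected there
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  slope <- unname(co["force"])
  sgn <- if (slope >= 0) 1L else -1L
  k0 <- exp(unname(co["(Intercept)"]))
  bell_params(
    k0 = k0, x = abs(slope) * thermal_energy, sign = sgn,
    k0_err = k0 * unname(se["(Intercept)"]),
    x_err = unname(se["force"]) * thermal_energy,
    n_events = if (!is.null(rates$n_events)) sum(rates$n_events) else
      NA_integer_
  )
}

#' Fit the Evans-Ritchie distribution to observed rupture forces
#'
#' Maximum-likelihood fit of the Bell/Evans-Ritchie rupture-force density
#' over (k0, x), parameterized in logs to preserve positivity. A binned
#' least-squares mode (default 1 pN left-closed bins) is available for
#' parity with histogram-based fitting. Standard errors are estimated by a
#' nonparametric bootstrap.
#'
#' @param forces Numeric vector of rupture forces, pN (>= 20 values).
#' @param loading_rate Loading rate, pN/s.
#' @param thermal_energy k_BT, pN nm.
#' @param method `"mle"` (default) or `"histogram"`.
#' @param bin_width Histogram bin width in pN (histogram method only).
#' @param n_boot Bootstrap resamples for standard errors (0 disables).
#' @param seed Optional seed for the bootstrap.
#' @return A [bell_params()] object with `k0_err`, `x_err` and `n_events`;
#'   the optimizer details are attached as attribute `"fit"`.
#' @export
fit_ramp_distribution <- function(forces, loading_rate, thermal_energy = 4.1,
                                  method = c("mle", "histogram"),
                                  bin_width = 1, n_boot = 200, seed = NULL) {
  method <- match.arg(method)
  forces <- forces[is.finite(forces)]
  if (length(forces) < 20) {
    stop_invalid("fit_ramp_distribution needs >= 20 rupture forces")
  }
  check_scalar_positive(loading_rate, "loading_rate")

  theta0 <- ramp_fit_init(forces, loading_rate, thermal_energy)
  fit_once <- function(f, theta_init) {
    obj <- switch(method,
      mle = function(theta) {
        bp <- bell_params(exp(theta[1]), exp(theta[2]))
        -sum(log(pmax(evans_ritchie_pdf(f, bp, loading_rate, thermal_energy),
                      1e-300)))
      },
      histogram = {
        brks <- seq(floor(min(f)), ceiling(max(f)) + bin_width, by = bin_width)
        h <- graphics::hist(f, breaks = brks, right = FALSE, plot = FALSE)
        function(theta) {
          bp <- bell_params(exp(theta[1]), exp(theta[2]))
          sum((h$density -
                 evans_ritchie_pdf(h$mids, bp, loading_rate,
                                   thermal_energy))^2)
        }
      })
    stats::optim(theta_init, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
  }
  opt <- fit_once(forces, theta0)
  if (opt$convergence != 0) {
    stop_invalid("ramp-distribution fit did not converge (optim code ",
                 opt$convergence, "): ", opt$message %||% "")
  }
  k0 <- exp(opt$par[1]); x <- exp(opt$par[2])
  k0_err <- NA_real_; x_err <- NA_real_
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        f <- sample(forces, replace = TRUE)
        b <- fit_once(f, opt$par)
        exp(b$par)
      }, numeric(2))
    })
    k0_err <- stats::sd(boots[1, ])
    x_err <- stats::sd(boots[2, ])
  }
  out <- bell_params(k0, x, sign = 1L, k0_err = k0_err, x_err = x_err,
                     n_events = length(forces))
  attr(out, "fit") <- list(method = method, loading_rate = loading_rate,
                           value = opt$value, counts = opt$counts,
                           n = length(forces), bin_width = bin_width,
                           n_boot = n_boot)
  out
}

# Moment-based starting values: the Evans-Ritchie density is Gumbel-like
# with scale k_BT/x, so sd(F) ~ 1.2825 k_BT / x; k0 then follows from the
# mode relation evaluated at the sample median.
ramp_fit_init <- function(forces, loading_rate, thermal_energy) {
  s <- stats::sd(forces)
  x0 <- min(max(1.2825 * thermal_energy / max(s, 0.1), 0.05), 10)
  fstar <- stats::median(forces)
  k00 <- x0 * loading_rate / thermal_energy * exp(-fstar * x0 / thermal_energy)
  c(log(max(k00, 1e-8)), log(x0))
}

#' Coexistence (critical) force of a folding/unfolding rate-law pair
#'
#' Force at which the Bell unfolding and folding rates are equal,
#' f_c = k_BT log(k_f0 / k_u0) / (x_u + x_f).
#'
#' @param unfold A [bell_params()] with `sign = +1`.
#' @param fold A [bell_params()] with `sign = -1`.
#' @param thermal_energy k_BT, pN nm.
#' @return Force in pN; 0 (with a warning) when the folding rate never
#'   exceeds the unfolding rate.
#' @export
critical_force <- function(unfold, fold, thermal_energy = 4.1) {
  stopifnot(inherits(unfold, "bell_params"), inherits(fold, "bell_params"))
  if (unfold$sign != 1L || fold$sign != -1L) {
    stop_invalid("critical_force expects an unfolding and a folding branch")
  }
  if (fold$k0 <= unfold$k0) {
    warning("k_f0 <= k_u0: construct is always unfolded; returning 0",
            call. = FALSE)
    return(0)
  }
  thermal_energy * log(fold$k0 / unfold$k0) / (unfold$x + fold$x)
}

#' Barrier height from a zero-force rate constant
#'
#' Arrhenius/Kramers inversion dG* = k_BT log(k* / k0) with attempt rate k*.
#'
#' @param k0 Zero-force rate constant, 1/s.
#' @param attempt_rate Intrinsic attempt rate k*, 1/s (default 1e6).
#' @return Barrier height in k_BT units.
#' @examples
#' barrier_height(3e-2) # ~ 17.3 k_BT
#' @export
barrier_height <- function(k0, attempt_rate = 1e6) {
  check_scalar_positive(k0, "k0")
  check_scalar_positive(attempt_rate, "attempt_rate")
  if (k0 > attempt_rate) {
    stop_invalid("k0 (", k0, ") exceeds the attempt rate (", attempt_rate,
                 "): barrier would be negative")
  }
  log(attempt_rate / k0)
}

#' Build a rate-estimate record
#'
#' One rate constant measured at one force, with its uncertainty and the
#' number of dwell events behind it.
#'
#' @param force Force, pN.
#' @param rate Rate, 1/s.
#' @param stderr Standard error of the rate, 1/s.
#' @param n_events Number of events.
#' @return A one-row data frame of class `rate_estimate`.
#' @export
rate_estimate <- function(force, rate, stderr = NA_real_,
                          n_events = NA_integer_) {
  stopifnot(rate > 0, is.na(n_events) || n_events >= 1)
  structure(data.frame(force = force, rate = rate, stderr = stderr,
                       n_events = as.integer(n_events)),
            class = c("rate_estimate", "data.frame"))
}
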