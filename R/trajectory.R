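# Trajectory analysis: smoothing, two-Gaussian occupancy fits, hidden-Markov
# segmentation, dwell-time extraction, exponential survival fits, and
# change-point step detection.

get_heights <- function(x) {
  if (is.data.frame(x)) {
    if (!"height_nm" %in% names(x)) stop_invalid("no `height_nm` column")
    x$height_nm
  } else if (is.numeric(x)) {
    x
  } else {
    stop_invalid("expected a trajectory or a numeric height vector")
  }
}

#' Moving-average smoothing
#'
#' Centered moving average with shrinking windows at the edges, so the
#' output has the same length as the input. A window of 20 samples at
#' 200 Hz corresponds to the 0.1 s display smoothing customary for
#' magnetic-tweezers bead-height records.
#'
#' @param x A trajectory or numeric height vector.
#' @param window Window size in samples (>= 1).
#' @return Numeric vector of smoothed heights, same length as the input.
#' @export
smooth_height <- function(x, window = 20) {
  h <- get_heights(x)
  n <- length(h)
  if (window < 1) stop_invalid("`window` must be >= 1")
  if (window > n) stop_invalid("`window` (", window,
                               ") exceeds trace length (", n, ")")
  window <- as.integer(window)
  if (window == 1L) return(h)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  cs <- cumsum(c(0, h))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Two-Gaussian occupancy fit of a height histogram
#'
#' Expectation-maximization fit of a two-component Gaussian mixture to
#' (smoothed) bead heights, giving the folded and unfolded peak positions,
#' widths, and the unfolded-state weight, which estimates the unfolding
#' probability P_u at the hold force.
#'
#' @param x A trajectory or numeric vector of (smoothed) heights
#'   (>= 1000 samples).
#' @param max_iter,tol EM controls.
#' @return An object of class `occupancy_fit`: `mean_N`, `mean_U`,
#'   `sigma_N`, `sigma_U`, `weight_U` (with `mean_U > mean_N`).
#' @export
fit_occupancy <- function(x, max_iter = 500, tol = 1e-10) {
  h <- get_heights(x)
  if (length(h) < 1000) {
    stop_invalid("fit_occupancy needs >= 1000 samples")
  }
  # initialize from the two best-separated modes of a kernel density
  # estimate, falling back to the 20/80 quantiles
  d <- stats::density(h, n = 512)
  pk <- which(diff(sign(diff(d$y))) == -2) + 1L
  if (length(pk) >= 2) {
    pk <- pk[order(d$y[pk], decreasing = TRUE)]
    sep <- abs(d$x[pk] - d$x[pk[1]])
    second <- pk[which(sep > stats::sd(h) / 2)[1]]
    if (is.na(second)) second <- pk[2]
    mu <- sort(c(d$x[pk[1]], d$x[second]))
  } else {
    mu <- unname(stats::quantile(h, c(0.2, 0.8)))
  }
  sg <- rep(max(stats::sd(h) / 2, 1e-3), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(h, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(h, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(r1 * h) / n1, sum(r2 * h) / n2)
    sg <- sqrt(pmax(c(sum(r1 * (h - mu[1])^2) / n1,
                      sum(r2 * (h - mu[2])^2) / n2), 1e-6))
    w <- c(n1, n2) / length(h)
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  ord <- order(mu)
  mu <- mu[ord]; sg <- sg[ord]; w <- w[ord]
  pooled <- sqrt(mean(sg^2))
  mixpdf <- function(z) w[1] * stats::dnorm(z, mu[1], sg[1]) +
    w[2] * stats::dnorm(z, mu[2], sg[2])
  if ((mu[2] - mu[1]) < 0.5 * pooled) {
    stop_invalid("degenerate occupancy fit: component means separated by ",
                 sprintf("%.3g", mu[2] - mu[1]), " nm < 0.5 pooled sigma (",
                 sprintf("%.3g", 0.5 * pooled), " nm)")
  }
  # a true two-state histogram dips between the peaks; a split fit of a
  # unimodal cloud does not
  if (mixpdf(mean(mu)) > 0.8 * min(mixpdf(mu[1]), mixpdf(mu[2]))) {
    stop_invalid("degenerate occupancy fit: no density dip between the ",
                 "fitted components (single-state signal?)")
  }
  structure(list(mean_N = mu[1], mean_U = mu[2],
                 sigma_N = sg[1], sigma_U = sg[2],
                 weight_U = w[2]),
            class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf(
    "Occupancy fit: N = %.2f (sd %.2f) nm, U = %.2f (sd %.2f) nm, P_u = %.3f\n",
    x$mean_N, x$sigma_N, x$mean_U, x$sigma_U, x$weight_U))
  invisible(x)
}

#' Hidden-Markov segmentation of a two-state trajectory
#'
#' Two-state Gaussian-emission hidden Markov model fitted by Baum-Welch on
#' the raw (unsmoothed) heights, initialized from a two-Gaussian occupancy
#' fit of the smoothed trace, and decoded by Viterbi. States are ordered by
#' emission mean, so `"N"` is always the lower-height state and label
#' swapping cannot occur.
#'
#' @param x A trajectory or numeric height vector.
#' @param init_window Smoothing window (samples) used only for the
#'   initialization fit.
#' @param self_prob Initial self-transition probability.
#' @param max_iter Maximum Baum-Welch iterations (error if exceeded without
#'   convergence).
#' @param tol Relative log-likelihood convergence tolerance.
#' @return A list of class `hmm_fit`: `states` (character `"N"`/`"U"` per
#'   sample), `mean_N`, `mean_U`, `sigma_N`, `sigma_U`, transition matrix
#'   `A`, `loglik`, `iterations`.
#' @export
hmm_segment <- function(x, init_window = 20, self_prob = 0.995,
                        max_iter = 500, tol = 1e-8) {
  h <- get_heights(x)
  hs <- smooth_height(h, min(init_window, length(h)))
  # the initialization fit only needs approximate peaks: subsample long traces
  if (length(hs) > 20000) {
    hs <- hs[seq(1L, length(hs), length.out = 20000L)]
  }
  occ <- fit_occupancy(hs)
  sd0 <- max(stats::sd(h) / 2, occ$sigma_N, 0.5)
  fit <- hmm_em_cpp(h,
                    mu_init = c(occ$mean_N, occ$mean_U),
                    sd_init = c(sd0, sd0),
                    A_init = matrix(c(self_prob, 1 - self_prob,
                                      1 - self_prob, self_prob),
                                    2, 2, byrow = TRUE),
                    pi_init = c(1 - occ$weight_U, occ$weight_U),
                    max_iter = as.integer(max_iter), tol = tol)
  if (!fit$converged) {
    stop_invalid("Baum-Welch did not converge in ", max_iter,
                 " iterations (last loglik ",
                 sprintf("%.6g", fit$loglik), ")")
  }
  ord <- order(fit$mu)
  path <- hmm_viterbi_cpp(h, fit$mu[ord], fit$sd[ord],
                          fit$A[ord, ord, drop = FALSE], fit$pi[ord])
  structure(list(states = ifelse(path == 0L, "N", "U"),
                 mean_N = fit$mu[ord][1], mean_U = fit$mu[ord][2],
                 sigma_N = fit$sd[ord][1], sigma_U = fit$sd[ord][2],
                 A = fit$A[ord, ord, drop = FALSE],
                 loglik = fit$loglik, iterations = fit$iterations,
                 loglik_trace = fit$loglik_trace),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf(
    "2-state HMM: N = %.2f nm, U = %.2f nm (sd %.2f/%.2f), %d EM iterations\n",
    x$mean_N, x$mean_U, x$sigma_N, x$sigma_U, x$iterations))
  invisible(x)
}

#' Extract dwell records from a decoded state path
#'
#' Run-length encodes the state sequence; the first and last dwells touch
#' the trajectory boundaries and are flagged censored.
#'
#' @param states Character vector of per-sample states (`"N"`/`"U"`).
#' @param sampling_rate Sampling rate, Hz.
#' @param force Hold force to annotate, pN.
#' @param min_dwell Optional minimum dwell duration, s; shorter dwells are
#'   dropped (default: keep all).
#' @return A data frame of class `dwell_records` with columns `state`,
#'   `duration_s`, `force_pN`, `censored` (touches either boundary), and the
#'   finer flags `censored_start`/`censored_end`. Only an end-censored dwell
#'   lacks an observed transition; a start-censored dwell still ends in one,
#'   which matters for censoring-aware rate estimation.
#' @export
extract_dwells <- function(states, sampling_rate = 200, force = NA_real_,
                           min_dwell = 0) {
  if (inherits(states, "hmm_fit")) states <- states$states
  r <- rle(as.character(states))
  n <- length(r$lengths)
  out <- data.frame(state = r$values,
                    duration_s = r$lengths / sampling_rate,
                    force_pN = force,
                    censored = seq_len(n) %in% c(1L, n),
                    censored_start = seq_len(n) == 1L,
                    censored_end = seq_len(n) == n,
                    stringsAsFactors = FALSE)
  if (min_dwell > 0) out <- out[out$duration_s >= min_dwell, , drop = FALSE]
  structure(out, class = c("dwell_records", "data.frame"))
}

#' Exponential survival fit of dwell times
#'
#' The default estimator is the exponential maximum-likelihood rate
#' k = n / sum(t) on uncensored dwells (standard error k/sqrt(n)); a
#' least-squares fit of the empirical cumulative distribution to
#' 1 - exp(-k t) is returned alongside for parity with histogram-style
#' analyses. With `min_dwell > 0` the time origin shifts by the detection
#' dead time, exploiting the memorylessness of the exponential so the
#' estimate stays unbiased when short dwells are unobservable.
#'
#' @param dwells A `dwell_records` data frame.
#' @param state Which state's dwells to fit (`"N"` gives the unfolding rate,
#'   `"U"` the folding rate).
#' @param min_events Minimum number of uncensored dwells required.
#' @param min_dwell Detection dead time, s: dwells shorter are discarded and
#'   the origin shifts accordingly.
#' @param include_censored If `TRUE`, use the censoring-aware MLE: every
#'   dwell contributes its duration to the exposure time, and every dwell
#'   that ends in an observed transition (including start-censored boundary
#'   dwells, which are valid fresh draws by memorylessness) counts as an
#'   event. The default (`FALSE`) uses fully-uncensored dwells only, which
#'   is simple but length-biased upward when dwells are long relative to
#'   the trace.
#' @return A [rate_estimate()] row with attribute `"cumulative_fit"` (the
#'   least-squares rate).
#' @export
survival_fit <- function(dwells, state = c("N", "U"), min_events = 10,
                         min_dwell = 0, include_censored = FALSE) {
  state <- match.arg(state)
  stopifnot(is.data.frame(dwells))
  d <- dwells[dwells$state == state, , drop = FALSE]
  if (min_dwell > 0) d <- d[d$duration_s >= min_dwell, , drop = FALSE]
  cen_end <- if (!is.null(d$censored_end)) d$censored_end else d$censored
  unc <- d[!d$censored, , drop = FALSE]
  if (include_censored) {
    n <- sum(!cen_end)
    exposure <- sum(pmax(d$duration_s - min_dwell, 0))
    if (n == 0) stop_invalid("all ", state, " dwells are censored")
  } else {
    if (nrow(unc) == 0) stop_invalid("all ", state, " dwells are censored")
    n <- nrow(unc)
    exposure <- sum(unc$duration_s - min_dwell)
  }
  if (n < min_events) {
    stop_invalid("survival_fit needs >= ", min_events,
                 " ", state, " dwell events (got ", n, ")")
  }
  k <- n / exposure
  # least-squares fit of the empirical cumulative to 1 - exp(-k t)
  ts <- if (include_censored) d$duration_s[!cen_end] else unc$duration_s
  ts <- sort(ts - min_dwell)
  ecdf_y <- seq_along(ts) / length(ts)
  ls <- stats::optimize(function(kk) sum((ecdf_y - (1 - exp(-kk * ts)))^2),
                        interval = c(k / 50, k * 50))$minimum
  out <- rate_estimate(force = unique(d$force_pN)[1], rate = k,
                       stderr = k / sqrt(n), n_events = n)
  attr(out, "cumulative_fit") <- ls
  out
}

#' Step detection by sliding two-window mean difference
#'
#' Scans the (smoothed) trace with two adjacent windows of `window` samples;
#' where the mean difference exceeds `threshold_sigma` times the expected
#' noise of that difference, a change point is declared at the local
#' extremum. Events closer than one window are merged, and the step size is
#' re-estimated from wider flanking windows (clipped at neighbouring events
#' and trace boundaries) for precision. Events too close to the boundaries
#' to support a full window are flagged unreliable.
#'
#' @param x A trajectory (or numeric height vector).
#' @param window Detection half-window, samples.
#' @param threshold_sigma Detection threshold in units of the noise s.d. of
#'   the two-window mean difference.
#' @param refine_factor The step re-estimation window is
#'   `refine_factor * window` samples on each side.
#' @param sampling_rate Sampling rate (taken from the trajectory when
#'   available).
#' @return A data frame with one row per event: `time_s`, `force_pN`,
#'   `step_nm` (signed), `reliable`.
#' @export
detect_steps <- function(x, window = 20, threshold_sigma = 5,
                         refine_factor = 4, sampling_rate = NULL) {
  h <- get_heights(x)
  n <- length(h)
  if (is.null(sampling_rate)) {
    sampling_rate <- attr(x, "sampling_rate") %||% 200
  }
  time <- if (is.data.frame(x) && "time_s" %in% names(x)) x$time_s else
    (seq_len(n) - 1L) / sampling_rate
  force <- if (is.data.frame(x) && "force_pN" %in% names(x)) x$force_pN else
    rep(NA_real_, n)
  empty <- data.frame(time_s = numeric(0), force_pN = numeric(0),
                      step_nm = numeric(0), reliable = logical(0))
  if (n < 2 * window + 1) return(empty)

  cs <- cumsum(c(0, h))
  win_mean <- function(lo, hi) (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  # difference between the window after and the window before position i
  idx <- seq.int(window, n - window)
  after <- win_mean(idx + 1L, idx + window)
  before <- win_mean(idx - window + 1L, idx)
  d <- after - before
  sigma <- stats::mad(diff(h)) / sqrt(2)
  if (sigma < 1e-12) sigma <- stats::sd(h) * 1e-6 + 1e-12
  thr <- threshold_sigma * sigma * sqrt(2 / window)
  hits <- which(abs(d) > thr)
  if (length(hits) == 0) return(empty)

  # group hits separated by less than one window; change point at max |d|
  grp <- cumsum(c(1L, diff(hits) > window))
  events <- vapply(split(hits, grp), function(g) g[which.max(abs(d[g]))],
                   integer(1))
  pos <- idx[events]

  res <- lapply(seq_along(pos), function(j) {
    i <- pos[j]
    wide <- refine_factor * window
    lo <- if (j > 1) max(pos[j - 1] + window, i - wide + 1L) else
      max(1L, i - wide + 1L)
    hi <- if (j < length(pos)) min(pos[j + 1] - window, i + wide) else
      min(n, i + wide)
    step <- win_mean(i + 1L, hi) - win_mean(lo, i)
    # a |d| peak clipped at the first/last scan position means the change
    # point may lie inside the boundary window: flag it unreliable
    at_edge <- i <= idx[1] || i >= idx[length(idx)]
    reliable <- !at_edge && (i - lo + 1L) >= window && (hi - i) >= window
    data.frame(time_s = time[i], force_pN = force[i], step_nm = step,
               reliable = reliable)
  })
  do.call(rbind, res)
}
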