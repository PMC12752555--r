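# Synthetic magnetic-tweezers trajectories with known ground truth: exact
# Gillespie two-state hopping under constant force, closed-form
# time-inhomogeneous sampling under force ramps, and concatenated holds for
# force jumps.  Emulates 200 Hz bead-height recordings of a two-state
# protein with Gaussian tracking noise.

#' Force protocols
#'
#' Constructors for the three force protocols the simulator understands:
#' a constant hold, a linear ramp (one or two legs), and a schedule of
#' instantaneous force jumps.
#'
#' @param force,hold_forces Hold force(s), pN (within \[0.1, 60\]).
#' @param duration,durations Hold duration(s), s.
#' @param f_start,f_max Ramp start and turnaround forces, pN.
#' @param rate Magnitude of the loading rate, pN/s.
#' @param relax If `TRUE` the ramp is followed by the mirror-image unloading
#'   leg back to `f_start`.
#' @return An object of class `force_protocol`.
#' @name force_protocol
NULL

check_protocol_force <- function(f) {
  if (any(f < 0.1) || any(f > 60)) {
    stop_invalid("protocol forces must lie within [0.1, 60] pN")
  }
  invisible(f)
}

#' @rdname force_protocol
#' @export
force_protocol_constant <- function(force, duration) {
  check_protocol_force(force)
  check_scalar_positive(duration, "duration")
  structure(list(kind = "constant", forces = force, durations = duration),
            class = "force_protocol")
}

#' @rdname force_protocol
#' @export
force_protocol_ramp <- function(f_start = 2, f_max = 42, rate = 1,
                                relax = TRUE) {
  check_protocol_force(c(f_start, f_max))
  check_scalar_positive(rate, "rate")
  if (f_max <= f_start) stop_invalid("`f_max` must exceed `f_start`")
  legs <- list(list(f_start = f_start, f_end = f_max, rate = rate))
  if (relax) {
    legs <- c(legs, list(list(f_start = f_max, f_end = f_start, rate = -rate)))
  }
  structure(list(kind = "ramp", legs = legs), class = "force_protocol")
}

#' @rdname force_protocol
#' @export
force_protocol_jump <- function(hold_forces, durations) {
  check_protocol_force(hold_forces)
  if (length(hold_forces) != length(durations) || any(durations <= 0)) {
    stop_invalid("`hold_forces` and `durations` must match and be positive")
  }
  structure(list(kind = "jump", forces = hold_forces, durations = durations),
            class = "force_protocol")
}

new_trajectory <- function(time, force, height, state, sampling_rate,
                           construct_id, protocol, seed, events = NULL) {
  df <- data.frame(time_s = time, force_pN = force, height_nm = height,
                   true_state = state, stringsAsFactors = FALSE)
  structure(df,
            class = c("trajectory", "data.frame"),
            sampling_rate = sampling_rate,
            construct_id = construct_id,
            protocol = protocol,
            seed = seed,
            events = events)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d samples at %g Hz (%.4g s), protocol '%s'%s\n",
              nrow(x), attr(x, "sampling_rate"),
              nrow(x) / attr(x, "sampling_rate"),
              attr(x, "protocol")$kind %||% "?",
              if (!is.null(attr(x, "construct_id")))
                paste0(", construct ", attr(x, "construct_id")) else ""))
  invisible(x)
}

# Tracking-noise generator: i.i.d. Gaussian by default, or a stationary
# Ornstein-Uhlenbeck process with the given corner frequency (Hz) whose
# marginal s.d. still equals `sigma`.
gen_noise <- function(n, sigma, corner_hz, sampling_rate) {
  if (sigma <= 0) return(numeric(n))
  if (is.null(corner_hz)) return(stats::rnorm(n, 0, sigma))
  a <- exp(-2 * pi * corner_hz / sampling_rate)
  innov <- stats::rnorm(n, 0, sigma * sqrt(1 - a^2))
  innov[1] <- stats::rnorm(1, 0, sigma)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# --- exact homogeneous Gillespie over piecewise-constant force segments ----

sim_segments_core <- function(model, forces, durations, sampling_rate,
                              noise_sigma, baseline_drift, state0,
                              noise_corner = NULL, force_scale = 1) {
  t_end <- sum(durations)
  seg_start <- cumsum(c(0, durations))[seq_along(durations)]
  n <- floor(t_end * sampling_rate)
  time <- (seq_len(n) - 1L) / sampling_rate
  seg_of <- findInterval(time, seg_start)
  force_samples <- forces[seg_of]

  trans_t <- numeric(0)
  state <- state0
  t <- 0
  for (i in seq_along(forces)) {
    f <- forces[i] * force_scale
    ku <- unfolding_rate(model, f)
    kf <- folding_rate(model, f)
    if (max(ku, kf) > sampling_rate / 2) {
      warning(sprintf(
        "mean dwell shorter than 2 samples at %.3g pN (undersampled)", f),
        call. = FALSE)
    }
    seg_end <- seg_start[i] + durations[i]
    repeat {
      rate <- if (state == "N") ku else kf
      if (rate <= 0) { t <- seg_end; break }
      dwell <- stats::rexp(1, rate)
      if (t + dwell >= seg_end) { t <- seg_end; break }
      t <- t + dwell
      trans_t <- c(trans_t, t)
      state <- if (state == "N") "U" else "N"
      if (length(trans_t) > 1e6) stop_invalid("transition cap exceeded")
    }
  }

  n_before <- findInterval(time, trans_t)
  is_u <- xor(state0 == "U", n_before %% 2L == 1L)
  steps <- step_size(forces * force_scale, model$elasticity)[seg_of]
  height <- baseline_drift * time + ifelse(is_u, steps, 0) +
    gen_noise(n, noise_sigma, noise_corner, sampling_rate)
  list(time = time, force = force_samples, height = height,
       state = ifelse(is_u, "U", "N"),
       transitions = trans_t, final_state = state)
}

#' Simulate an equilibrium constant-force trajectory
#'
#' Exact Gillespie alternation between the native (N) and unfolded (U)
#' states with Bell-model rates at the hold force; the bead height is the
#' state-dependent step size plus i.i.d. Gaussian tracking noise (and an
#' optional linear baseline drift).
#'
#' @param model A [construct_model()].
#' @param force Hold force, pN.
#' @param duration Duration, s.
#' @param sampling_rate Sampling rate, Hz (default 200).
#' @param noise_sigma Gaussian noise s.d., nm (default 6).
#' @param baseline_drift Linear drift, nm/s.
#' @param seed Integer seed (required).
#' @param state0 Initial state, `"N"` or `"U"`.
#' @param noise_corner Optional corner frequency (Hz): when set, tracking
#'   noise is a stationary Ornstein-Uhlenbeck process of marginal s.d.
#'   `noise_sigma` instead of white Gaussian noise.
#' @param force_scale_sd Optional relative force-calibration error: each
#'   trace draws one scale factor ~ Normal(1, `force_scale_sd`) applied to
#'   the true force (rates and step sizes) while the nominal force is
#'   recorded, emulating per-tether force uncertainty. Default 0 (off).
#' @return A `trajectory` data frame (`time_s`, `force_pN`, `height_nm`,
#'   `true_state`) with the transition times in `attr(, "events")`.
#' @export
simulate_constant_force <- function(model, force, duration,
                                    sampling_rate = 200, noise_sigma = 6,
                                    baseline_drift = 0, seed, state0 = "N",
                                    noise_corner = NULL,
                                    force_scale_sd = 0) {
  stopifnot(inherits(model, "construct_model"))
  check_protocol_force(force)
  sim <- with_seed(seed, {
    scale <- if (force_scale_sd > 0)
      1 + stats::rnorm(1, 0, force_scale_sd) else 1
    sim_segments_core(model, force, duration, sampling_rate, noise_sigma,
                      baseline_drift, state0, noise_corner, scale)
  })
  new_trajectory(sim$time, sim$force, sim$height, sim$state, sampling_rate,
                 model$construct_id,
                 force_protocol_constant(force, duration), seed,
                 events = data.frame(time_s = sim$transitions,
                                     force_pN = rep(force,
                                                    length(sim$transitions))))
}

#' Simulate a force-jump trajectory
#'
#' Concatenated constant-force holds with instantaneous force changes; the
#' protein state carries over between segments. A single-segment schedule is
#' identical (given the same seed) to [simulate_constant_force()].
#'
#' @param model A [construct_model()].
#' @param protocol A `force_protocol_jump()` object, or `hold_forces` and
#'   `durations` directly.
#' @param hold_forces,durations Alternative to `protocol`.
#' @inheritParams simulate_constant_force
#' @return A `trajectory`; `attr(, "events")` holds the transition times.
#' @export
simulate_force_jump <- function(model, protocol = NULL, hold_forces = NULL,
                                durations = NULL, sampling_rate = 200,
                                noise_sigma = 6, baseline_drift = 0, seed,
                                state0 = "N", noise_corner = NULL,
                                force_scale_sd = 0) {
  stopifnot(inherits(model, "construct_model"))
  if (is.null(protocol)) {
    protocol <- force_protocol_jump(hold_forces, durations)
  }
  stopifnot(identical(protocol$kind, "jump"))
  sim <- with_seed(seed, {
    scale <- if (force_scale_sd > 0)
      1 + stats::rnorm(1, 0, force_scale_sd) else 1
    sim_segments_core(model, protocol$forces, protocol$durations,
                      sampling_rate, noise_sigma, baseline_drift, state0,
                      noise_corner, scale)
  })
  seg_start <- cumsum(c(0, protocol$durations))
  seg_of <- findInterval(sim$transitions, seg_start[seq_along(protocol$forces)])
  new_trajectory(sim$time, sim$force, sim$height, sim$state, sampling_rate,
                 model$construct_id, protocol, seed,
                 events = data.frame(time_s = sim$transitions,
                                     force_pN = protocol$forces[seg_of]))
}

# --- exact inhomogeneous sampling for linear ramps -------------------------

# Next transition force for a single Bell branch along a linear ramp from
# F1 towards F2 at rate r, given remaining exponential budget E.
# Integrated hazard: Lambda = k0 (e^{aF2} - e^{aF1}) / (a r), a = sign*x/beta.
branch_next_force <- function(k0, x, sgn, beta, F1, F2, r, E) {
  a <- sgn * x / beta
  cap <- k0 * (exp(a * F2) - exp(a * F1)) / (a * r)
  if (E >= cap) return(list(hit = FALSE, spent = cap))
  list(hit = TRUE, force = log(exp(a * F1) + E * a * r / k0) / a)
}

# Same, for the construct's min-of-two-branches unfolding law: split the
# force interval at the regime boundary so each piece is a single Bell law.
unfold_next_force <- function(model, F1, F2, r, E) {
  beta <- model$elasticity$thermal_energy
  fb <- model$regime_boundary
  pts <- sort(unique(c(F1, F2, if (min(F1, F2) < fb && max(F1, F2) > fb) fb)),
              decreasing = r < 0)
  for (i in seq_len(length(pts) - 1L)) {
    fa <- pts[i]; fbnd <- pts[i + 1L]
    mid <- (fa + fbnd) / 2
    br <- if (mid < fb) model$low_force else model$high_force
    res <- branch_next_force(br$k0, br$x, 1, beta, fa, fbnd, r, E)
    if (res$hit) return(res)
    E <- E - res$spent
  }
  list(hit = FALSE)
}

fold_next_force <- function(model, F1, F2, r, E) {
  beta <- model$elasticity$thermal_energy
  branch_next_force(model$folding$k0, model$folding$x, -1, beta, F1, F2, r, E)
}

#' Simulate a force-ramp trajectory
#'
#' The force grows (and optionally relaxes) linearly in time; transitions
#' are drawn exactly by inverting the closed-form integrated hazard of the
#' Bell rate laws along the ramp, so the first-unfolding force follows the
#' Evans-Ritchie distribution of the construct's unfolding law exactly.
#' Heights use the force-dependent step size at each sample.
#'
#' @param model A [construct_model()].
#' @param protocol A `force_protocol_ramp()` object.
#' @inheritParams simulate_constant_force
#' @return A `trajectory`; `attr(, "events")` is a data frame of the true
#'   transition times, forces and directions (`"unfold"`/`"refold"`).
#' @export
simulate_ramp <- function(model, protocol = force_protocol_ramp(),
                          sampling_rate = 200, noise_sigma = 6,
                          baseline_drift = 0, seed, state0 = "N",
                          noise_corner = NULL, force_scale_sd = 0) {
  stopifnot(inherits(model, "construct_model"),
            identical(protocol$kind, "ramp"))
  sim <- with_seed(seed, {
    scale <- if (force_scale_sd > 0)
      1 + stats::rnorm(1, 0, force_scale_sd) else 1
    legs <- protocol$legs
    leg_dur <- vapply(legs, function(l) (l$f_end - l$f_start) / l$rate,
                      numeric(1))
    t_end <- sum(leg_dur)
    leg_start <- cumsum(c(0, leg_dur))[seq_along(legs)]
    n <- floor(t_end * sampling_rate)
    time <- (seq_len(n) - 1L) / sampling_rate
    leg_of <- findInterval(time, leg_start)
    force_samples <- numeric(n)
    for (j in seq_along(legs)) {
      idx <- which(leg_of == j)
      force_samples[idx] <- legs[[j]]$f_start +
        legs[[j]]$rate * (time[idx] - leg_start[j])
    }

    # the kinetics and step sizes see the (possibly mis-calibrated) true
    # force scale; recorded forces stay nominal
    state <- state0
    ev_t <- numeric(0); ev_f <- numeric(0); ev_dir <- character(0)
    for (j in seq_along(legs)) {
      l <- legs[[j]]
      fcur <- l$f_start * scale
      repeat {
        E <- stats::rexp(1)
        res <- if (state == "N") {
          unfold_next_force(model, fcur, l$f_end * scale, l$rate * scale, E)
        } else {
          fold_next_force(model, fcur, l$f_end * scale, l$rate * scale, E)
        }
        if (!res$hit) break
        fcur <- res$force
        tev <- leg_start[j] + (fcur / scale - l$f_start) / l$rate
        ev_t <- c(ev_t, tev); ev_f <- c(ev_f, fcur / scale)
        ev_dir <- c(ev_dir, if (state == "N") "unfold" else "refold")
        state <- if (state == "N") "U" else "N"
        if (length(ev_t) > 1e5) stop_invalid("transition cap exceeded")
      }
    }

    n_before <- findInterval(time, ev_t)
    is_u <- xor(state0 == "U", n_before %% 2L == 1L)
    sf <- step_size_fun(model$elasticity,
                        fmax = scale * (max(vapply(legs, function(l)
                          max(l$f_start, l$f_end), numeric(1))) + 1))
    height <- baseline_drift * time +
      ifelse(is_u, sf(force_samples * scale), 0) +
      gen_noise(n, noise_sigma, noise_corner, sampling_rate)
    list(time = time, force = force_samples, height = height,
         state = ifelse(is_u, "U", "N"),
         events = data.frame(time_s = ev_t, force_pN = ev_f,
                             direction = ev_dir, stringsAsFactors = FALSE))
  })
  new_trajectory(sim$time, sim$force, sim$height, sim$state, sampling_rate,
                 model$construct_id, protocol, seed, events = sim$events)
}

#' Simulate a trajectory under any force protocol
#'
#' Dispatches on the protocol kind to [simulate_constant_force()],
#' [simulate_ramp()] or [simulate_force_jump()].
#'
#' @param model A [construct_model()].
#' @param protocol A [force_protocol] object.
#' @inheritParams simulate_constant_force
#' @return A `trajectory`.
#' @export
simulate_trajectory <- function(model, protocol, sampling_rate = 200,
                                noise_sigma = 6, baseline_drift = 0, seed,
                                state0 = "N", noise_corner = NULL,
                                force_scale_sd = 0) {
  stopifnot(inherits(protocol, "force_protocol"))
  switch(protocol$kind,
    constant = simulate_constant_force(model, protocol$forces,
                                       protocol$durations, sampling_rate,
                                       noise_sigma, baseline_drift, seed,
                                       state0, noise_corner,
                                       force_scale_sd),
    ramp = simulate_ramp(model, protocol, sampling_rate, noise_sigma,
                         baseline_drift, seed, state0, noise_corner,
                         force_scale_sd),
    jump = simulate_force_jump(model, protocol,
                               sampling_rate = sampling_rate,
                               noise_sigma = noise_sigma,
                               baseline_drift = baseline_drift, seed = seed,
                               state0 = state0, noise_corner = noise_corner,
                               force_scale_sd = force_scale_sd),
    stop_invalid("unknown protocol kind: ", protocol$kind))
}
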