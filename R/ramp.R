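# Constant-loading-rate analysis: detect rupture events across ramp traces,
# build the unfolding-force distribution, and fit it.

#' Collect rupture forces from force-ramp trajectories
#'
#' Runs [detect_steps()] on each trace and keeps the first qualifying event
#' per ramp leg: a positive step on a loading leg for `direction = "unfold"`,
#' a negative step on an unloading leg for `direction = "refold"`.
#'
#' @param trajectories A list of ramp `trajectory` objects (or a single one).
#' @param direction `"unfold"` or `"refold"`.
#' @param window,threshold_sigma Passed to [detect_steps()].
#' @return An object of class `rupture_set`: list with `forces` (pN),
#'   `loading_rate` (pN/s), `n_traces`, `construct_id`, `direction`.
#' @export
collect_ruptures <- function(trajectories, direction = c("unfold", "refold"),
                             window = 20, threshold_sigma = 5) {
  direction <- match.arg(direction)
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  if (length(trajectories) == 0) {
    return(structure(list(forces = numeric(0), loading_rate = NA_real_,
                          n_traces = 0L, construct_id = NA_character_,
                          direction = direction),
                     class = "rupture_set"))
  }
  want_sign <- if (direction == "unfold") 1 else -1
  loading_rate <- NA_real_
  construct_id <- NA_character_
  forces <- unlist(lapply(trajectories, function(tr) {
    prot <- attr(tr, "protocol")
    if (is.null(prot) || !identical(prot$kind, "ramp")) {
      stop_invalid("collect_ruptures needs ramp-protocol trajectories")
    }
    construct_id <<- attr(tr, "construct_id") %||% construct_id
    out <- numeric(0)
    leg_t0 <- 0
    for (l in prot$legs) {
      dur <- (l$f_end - l$f_start) / l$rate
      if (sign(l$rate) == want_sign) {
        if (is.na(loading_rate)) loading_rate <<- l$rate
        sel <- tr$time_s >= leg_t0 & tr$time_s < leg_t0 + dur
        ev <- detect_steps(tr[sel, , drop = FALSE], window = window,
                           threshold_sigma = threshold_sigma,
                           sampling_rate = attr(tr, "sampling_rate"))
        ev <- ev[sign(ev$step_nm) == want_sign & ev$reliable, , drop = FALSE]
        if (nrow(ev) > 0) out <- c(out, ev$force_pN[1])
      }
      leg_t0 <- leg_t0 + dur
    }
    out
  }))
  structure(list(forces = forces, loading_rate = loading_rate,
                 n_traces = length(trajectories),
                 construct_id = construct_id, direction = direction),
            class = "rupture_set")
}

#' @export
print.rupture_set <- function(x, ...) {
  cat(sprintf("Rupture set (%s): %d events from %d traces at %g pN/s\n",
              x$direction, length(x$forces), x$n_traces, x$loading_rate))
  invisible(x)
}

#' Normalized rupture-force histogram
#'
#' Left-closed bins of `bin_width` pN, normalized to unit area.
#'
#' @param ruptures A `rupture_set` or numeric force vector.
#' @param bin_width Bin width, pN.
#' @return A data frame with `mid`, `density`, `count` per bin.
#' @export
rupture_histogram <- function(ruptures, bin_width = 1) {
  forces <- if (inherits(ruptures, "rupture_set")) ruptures$forces else
    ruptures
  if (length(forces) == 0) stop_invalid("no rupture forces to bin")
  brks <- seq(floor(min(forces)), ceiling(max(forces)) + bin_width,
              by = bin_width)
  h <- graphics::hist(forces, breaks = brks, right = FALSE, plot = FALSE)
  data.frame(mid = h$mids, density = h$density, count = h$counts)
}

#' Fit a ramp experiment end to end
#'
#' Fits the Evans-Ritchie rupture-force distribution
#' ([fit_ramp_distribution()]) to a collected rupture set and reports the
#' fitted Bell parameters together with the most probable unfolding force of
#' the fit.
#'
#' @param ruptures A `rupture_set` (from [collect_ruptures()]) or a numeric
#'   vector of rupture forces (then `loading_rate` must be given).
#' @param loading_rate Loading rate, pN/s (taken from the rupture set when
#'   available).
#' @param thermal_energy k_BT, pN nm.
#' @param ... Passed to [fit_ramp_distribution()].
#' @return A list of class `ramp_analysis`: `params` ([bell_params()]),
#'   `most_probable_force` (pN), `n_events`, `loading_rate`, `construct_id`.
#' @export
analyze_ramp_experiment <- function(ruptures, loading_rate = NULL,
                                    thermal_energy = 4.1, ...) {
  if (inherits(ruptures, "rupture_set")) {
    loading_rate <- loading_rate %||% abs(ruptures$loading_rate)
    construct_id <- ruptures$construct_id
    forces <- ruptures$forces
  } else {
    construct_id <- NA_character_
    forces <- ruptures
  }
  if (is.null(loading_rate)) stop_invalid("`loading_rate` is required")
  fit <- fit_ramp_distribution(forces, loading_rate, thermal_energy, ...)
  structure(list(params = fit,
                 most_probable_force = most_probable_force(fit, loading_rate,
                                                           thermal_energy),
                 n_events = length(forces),
                 loading_rate = loading_rate,
                 construct_id = construct_id),
            class = "ramp_analysis")
}

#' @export
print.ramp_analysis <- function(x, ...) {
  cat(sprintf(
    "Ramp analysis (%s, %d events at %g pN/s):\n  k_u0 = %.3g 1/s, x_u = %.3g nm, F* = %.3g pN\n",
    x$construct_id, x$n_events, x$loading_rate,
    x$params$k0, x$params$x, x$most_probable_force))
  invisible(x)
}
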