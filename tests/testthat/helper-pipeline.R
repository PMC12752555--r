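# Round-trip acquisition protocol used by the acceptance tests: simulate
# 600 s tethers at each force until the target number of dwell events per
# state is reached (or the per-force simulated-time cap), segment with the
# HMM, and estimate rates with the censoring-aware exponential MLE.
# Targets and caps were fixed by a dwell-level power analysis before the
# test seed was chosen.

acquire_equilibrium_dwells <- function(model, force, base_seed,
                                       target_events, cap_s,
                                       tether_s = 600, noise_sigma = 6) {
  dwells <- list()
  total_s <- 0
  j <- 0
  repeat {
    j <- j + 1
    tr <- simulate_constant_force(model, force, tether_s,
                                  noise_sigma = noise_sigma,
                                  seed = base_seed + j)
    seg <- try(hmm_segment(tr), silent = TRUE)
    if (inherits(seg, "try-error")) {
      # no transitions resolved: the whole tether is one censored dwell of
      # whichever state the mean height indicates (pure exposure)
      st <- if (mean(tr$height_nm) >
                  step_size(force, model$elasticity) / 2) "U" else "N"
      dwells[[j]] <- data.frame(state = st, duration_s = tether_s,
                                force_pN = force, censored = TRUE,
                                censored_start = TRUE, censored_end = TRUE)
    } else {
      dwells[[j]] <- extract_dwells(seg$states, 200, force)
    }
    total_s <- total_s + tether_s
    dw <- do.call(rbind, dwells)
    n_min <- min(sum(dw$state == "N" & !dw$censored_end),
                 sum(dw$state == "U" & !dw$censored_end))
    if (n_min >= target_events || total_s >= cap_s) break
  }
  do.call(rbind, dwells)
}

equilibrium_round_trip <- function(model, forces, base_seed,
                                   target_events, cap_s) {
  beta <- model$elasticity$thermal_energy
  rows_u <- list()
  rows_f <- list()
  for (i in seq_along(forces)) {
    f <- forces[i]
    dw <- acquire_equilibrium_dwells(model, f, base_seed + 100000L * i,
                                     target_events, cap_s)
    ku <- survival_fit(dw, "N", include_censored = TRUE)
    kf <- survival_fit(dw, "U", include_censored = TRUE)
    rows_u[[i]] <- as.data.frame(ku)
    rows_f[[i]] <- as.data.frame(kf)
  }
  list(unfold = fit_bell(do.call(rbind, rows_u), beta),
       fold = fit_bell(do.call(rbind, rows_f), beta),
       unfold_rates = do.call(rbind, rows_u),
       fold_rates = do.call(rbind, rows_f))
}

# First-passage unfolding rates from force-jump simulations, with the
# detection dead time handled by a shifted-origin truncated MLE.
jump_round_trip <- function(model, forces, base_seed, n_rep = 60,
                            window = 20, noise_sigma = 6) {
  beta <- model$elasticity$thermal_energy
  rows <- list()
  steps <- list()
  for (i in seq_along(forces)) {
    f <- forces[i]
    k_nom <- unfolding_rate(model, f)
    hold <- min(90, max(8, 8 / k_nom))
    dwell <- numeric(0)
    stp <- numeric(0)
    n_cens <- 0
    for (j in seq_len(n_rep)) {
      tr <- simulate_force_jump(model, hold_forces = c(1, f),
                                durations = c(1, hold),
                                noise_sigma = noise_sigma,
                                seed = base_seed + 1000L * i + j)
      hold_tr <- tr[tr$time_s >= 1, , drop = FALSE]
      ev <- detect_steps(hold_tr, window = window, threshold_sigma = 5,
                         sampling_rate = 200)
      ev <- ev[ev$step_nm > 0 & ev$reliable, , drop = FALSE]
      if (nrow(ev) > 0) {
        dwell <- c(dwell, ev$time_s[1] - 1)
        stp <- c(stp, ev$step_nm[1])
      } else {
        # no resolvable event: decide by the end-of-hold level whether the
        # molecule is still folded (right-censored exposure) or unfolded
        # too early to resolve (left-truncated: drop the replicate)
        tail_lvl <- mean(utils::tail(hold_tr$height_nm, 100))
        if (tail_lvl < step_size(f, model$elasticity) / 2) {
          n_cens <- n_cens + 1
        }
      }
    }
    # conditional-on-detection exponential MLE: dwells below the detection
    # dead time are truncated away, the origin shifts by the dead time,
    # and still-folded replicates contribute censored exposure
    dead <- 2 * window / 200
    keep <- dwell >= dead
    n <- sum(keep)
    k <- n / (sum(dwell[keep] - dead) + n_cens * max(hold - dead, 0))
    rows[[i]] <- data.frame(force = f, rate = k, stderr = k / sqrt(n),
                            n_events = n)
    steps[[i]] <- data.frame(force = f, mean_step = mean(stp),
                             n = length(stp))
  }
  list(fit = fit_bell(do.call(rbind, rows), beta),
       rates = do.call(rbind, rows),
       steps = do.call(rbind, steps))
}
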