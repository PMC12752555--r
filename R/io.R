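# File formats and the reproducible pipeline runner: tab-separated
# trajectories with a JSON metadata sidecar, TSV dwell/rupture tables, and
# JSON results keyed by config + seed.

#' Write a trajectory to a tab-separated file
#'
#' Columns `time_s force_pN height_nm [true_state]`; metadata (sampling
#' rate, construct, protocol kind, seed) goes to a JSON sidecar
#' `<path>.json`. A `.gz` suffix triggers gzip compression.
#'
#' @param trajectory A `trajectory` object.
#' @param path Output path (`.tsv` or `.tsv.gz`).
#' @param sidecar Write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, sidecar = TRUE) {
  stopifnot(is.data.frame(trajectory))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(trajectory), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (sidecar) {
    meta <- list(sampling_rate = attr(trajectory, "sampling_rate"),
                 construct_id = attr(trajectory, "construct_id"),
                 protocol = attr(trajectory, "protocol")["kind"],
                 seed = attr(trajectory, "seed"),
                 n_samples = nrow(trajectory))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null")
  }
  invisible(path)
}

#' Read a trajectory from a tab-separated file
#'
#' Requires header columns `time_s`, `force_pN`, `height_nm`; an optional
#' `true_state` column is kept. Time must be strictly increasing with a
#' uniform sampling interval. Gzip-compressed files are read transparently.
#'
#' @param path Input path.
#' @return A `trajectory` data frame with the sampling rate as attribute.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("time_s", "force_pN", "height_nm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop_invalid("missing required column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    stop_invalid("time_s is not strictly increasing (row ",
                 which(dt <= 0)[1] + 1L, ")")
  }
  if (length(dt) > 0 && (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    stop_invalid("mixed sampling interval: dt ranges ",
                 sprintf("%.6g..%.6g s", min(dt), max(dt)))
  }
  sr <- if (length(dt) > 0) 1 / stats::median(dt) else NA_real_
  state <- if ("true_state" %in% names(df)) df$true_state else
    rep(NA_character_, nrow(df))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list()
  new_trajectory(df$time_s, df$force_pN, df$height_nm, state,
                 sampling_rate = meta$sampling_rate %||% sr,
                 construct_id = meta$construct_id %||% NA_character_,
                 protocol = list(kind = meta$protocol$kind %||% "unknown"),
                 seed = meta$seed %||% NA_integer_)
}

#' Default pipeline configuration
#'
#' A complete runnable configuration for [run_pipeline()], scaled so the
#' demo completes in well under five minutes on one CPU.
#'
#' @param construct Construct identifier (see [csp_constructs()]).
#' @param seed Integer seed (mandatory for any stochastic stage).
#' @param output_dir Output directory, or `NULL` to skip writing files.
#' @return A named list understood by [run_pipeline()].
#' @export
default_config <- function(construct = "LE-CSP-GS", seed = 1,
                           output_dir = NULL) {
  list(
    construct = construct,
    seed = seed,
    output_dir = output_dir,
    noise_sigma = 6,
    sampling_rate = 200,
    equilibrium = list(forces = 4:8, n_tethers = 4, duration_s = 500),
    ramp = list(n_traces = 80, f_start = 2, f_max = 42, rate = 1),
    jump = list(forces = c(12, 16, 20, 25, 30), n_replicates = 40,
                hold_s = 25, pre_force = 1, pre_s = 2),
    analysis = list(window = 20, threshold_sigma = 5, n_boot = 100)
  )
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop_invalid("config must be a list or a JSON path")
  if (is.null(config$seed)) stop_invalid("config validation: `seed` is required")
  if (is.null(config$construct) ||
      !config$construct %in% csp_constructs()) {
    stop_invalid("config validation: `construct` must be one of ",
                 paste(csp_constructs(), collapse = ", "))
  }
  defaults <- default_config(config$construct, config$seed)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (sub in names(defaults[[nm]])) {
        config[[nm]][[sub]] <- config[[nm]][[sub]] %||% defaults[[nm]][[sub]]
      }
    }
  }
  config
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> segment -> dwell/rate analysis -> Bell and
#' Evans-Ritchie fits -> landscape reconstruction for one construct, from a
#' single seeded configuration. Re-running with the same config reproduces
#' every number exactly. When `output_dir` is set, results are written as
#' JSON, dwell and rupture tables as TSV, and a run log records seeds and
#' event counts.
#'
#' @param config A configuration list (see [default_config()]) or a path to
#'   a JSON file with the same fields. `seed` and `construct` are mandatory.
#' @param verbose Emit stage-level progress messages.
#' @return A list of class `pipeline_report` with elements `config`,
#'   `equilibrium` (per-force rates and P_u), `low_force_fits`, `ramp`,
#'   `jump`, `high_force_fit`, `landscape`.
#' @export
run_pipeline <- function(config = default_config(), verbose = TRUE) {
  config <- validate_config(config)
  model <- csp_construct(config$construct)
  seed <- as.integer(config$seed)
  beta <- model$elasticity$thermal_energy
  win <- config$analysis$window
  thr <- config$analysis$threshold_sigma

  # --- equilibrium stage -------------------------------------------------
  eq <- config$equilibrium
  eq_rows <- list()
  dwell_tables <- list()
  for (i in seq_along(eq$forces)) {
    f <- eq$forces[i]
    dwells <- list()
    pu_hmm <- numeric(0)
    wsum <- 0
    for (j in seq_len(eq$n_tethers)) {
      tr <- simulate_constant_force(model, f, eq$duration_s,
                                    sampling_rate = config$sampling_rate,
                                    noise_sigma = config$noise_sigma,
                                    seed = seed + 1000L * i + j)
      seg <- try(hmm_segment(tr), silent = TRUE)
      if (inherits(seg, "try-error")) next
      dwells[[j]] <- extract_dwells(seg$states, config$sampling_rate, f)
      pu_hmm <- c(pu_hmm, mean(seg$states == "U"))
    }
    if (length(dwells) == 0) next
    dw <- do.call(rbind, dwells)
    dwell_tables[[length(dwell_tables) + 1L]] <- dw
    ku <- try(survival_fit(dw, "N"), silent = TRUE)
    kf <- try(survival_fit(dw, "U"), silent = TRUE)
    eq_rows[[length(eq_rows) + 1L]] <- data.frame(
      force = f,
      pu = mean(pu_hmm),
      ku = if (inherits(ku, "try-error")) NA_real_ else ku$rate,
      ku_se = if (inherits(ku, "try-error")) NA_real_ else ku$stderr,
      ku_n = if (inherits(ku, "try-error")) NA_integer_ else ku$n_events,
      kf = if (inherits(kf, "try-error")) NA_real_ else kf$rate,
      kf_se = if (inherits(kf, "try-error")) NA_real_ else kf$stderr,
      kf_n = if (inherits(kf, "try-error")) NA_integer_ else kf$n_events)
  }
  eq_table <- do.call(rbind, eq_rows)
  pipeline_log(verbose, "equilibrium: %d forces analysed, n=%d dwells",
               nrow(eq_table), sum(vapply(dwell_tables, nrow, integer(1))))

  unfold_rates <- with(eq_table[!is.na(eq_table$ku), ],
                       data.frame(force = force, rate = ku, stderr = ku_se,
                                  n_events = ku_n))
  fold_rates <- with(eq_table[!is.na(eq_table$kf), ],
                     data.frame(force = force, rate = kf, stderr = kf_se,
                                n_events = kf_n))
  low_fit <- try(fit_bell(unfold_rates, beta), silent = TRUE)
  fold_fit <- try(fit_bell(fold_rates, beta), silent = TRUE)
  if (inherits(low_fit, "try-error") || inherits(fold_fit, "try-error")) {
    stop_invalid("pipeline stage 'low-force fits' failed; ",
                 "equilibrium table preserved in the report")
  }

  # --- ramp stage --------------------------------------------------------
  rp <- config$ramp
  prot <- force_protocol_ramp(rp$f_start, rp$f_max, rp$rate)
  ramps <- lapply(seq_len(rp$n_traces), function(j) {
    simulate_ramp(model, prot, sampling_rate = config$sampling_rate,
                  noise_sigma = config$noise_sigma,
                  seed = seed + 500000L + j)
  })
  ruptures <- collect_ruptures(ramps, "unfold", window = win,
                               threshold_sigma = thr)
  pipeline_log(verbose, "ramp: n=%d ruptures collected from %d traces",
               length(ruptures$forces), rp$n_traces)
  ramp_fit <- analyze_ramp_experiment(ruptures, thermal_energy = beta,
                                      n_boot = config$analysis$n_boot,
                                      seed = seed + 7L)

  # --- force-jump stage --------------------------------------------------
  jp <- config$jump
  jump_rows <- list()
  jump_steps <- list()
  for (i in seq_along(jp$forces)) {
    f <- jp$forces[i]
    dwell <- numeric(0)
    steps <- numeric(0)
    n_cens <- 0
    for (j in seq_len(jp$n_replicates)) {
      tr <- simulate_force_jump(
        model, hold_forces = c(jp$pre_force, f),
        durations = c(jp$pre_s, jp$hold_s),
        sampling_rate = config$sampling_rate,
        noise_sigma = config$noise_sigma,
        seed = seed + 900000L + 1000L * i + j)
      hold <- tr[tr$time_s >= jp$pre_s, , drop = FALSE]
      ev <- detect_steps(hold, window = win, threshold_sigma = thr,
                         sampling_rate = config$sampling_rate)
      ev <- ev[ev$step_nm > 0 & ev$reliable, , drop = FALSE]
      if (nrow(ev) > 0) {
        dwell <- c(dwell, ev$time_s[1] - jp$pre_s)
        steps <- c(steps, ev$step_nm[1])
      } else if (mean(utils::tail(hold$height_nm, 100)) <
                   step_size(f, model$elasticity) / 2) {
        # still folded at the end of the hold: right-censored exposure;
        # unresolved early unfoldings are left-truncated and dropped
        n_cens <- n_cens + 1
      }
    }
    dead <- 2 * win / config$sampling_rate
    keep <- dwell >= dead
    if (sum(keep) >= 10) {
      k <- sum(keep) / (sum(dwell[keep] - dead) +
                          n_cens * max(jp$hold_s - dead, 0))
      jump_rows[[length(jump_rows) + 1L]] <- data.frame(
        force = f, rate = k, stderr = k / sqrt(sum(keep)),
        n_events = sum(keep))
    }
    jump_steps[[length(jump_steps) + 1L]] <-
      data.frame(force = f, mean_step = mean(steps), n = length(steps))
  }
  jump_rates <- do.call(rbind, jump_rows)
  high_fit <- fit_bell(jump_rates, beta)
  pipeline_log(verbose, "jump: %d forces, n=%d unfolding events",
               nrow(jump_rates), sum(jump_rates$n_events))

  # --- landscape ---------------------------------------------------------
  fitted_model <- construct_model(
    construct_id = paste0(config$construct, " (fitted)"),
    low_force = low_fit, high_force = high_fit, folding = fold_fit,
    elasticity = model$elasticity,
    attempt_rate = max(model$attempt_rate, low_fit$k0, high_fit$k0),
    regime_boundary = model$regime_boundary)
  landscape <- reconstruct_landscape(fitted_model)
  pu_fit <- try(fit_unfolding_probability(eq_table$force, eq_table$pu,
                                          model$elasticity), silent = TRUE)
  pipeline_log(verbose,
               "landscape: dG0 = %.2f k_BT, critical force %.2f pN",
               landscape$delta_g0, landscape$critical_force)

  report <- list(
    config = config,
    equilibrium = eq_table,
    low_force_fits = list(unfolding = low_fit, folding = fold_fit),
    ramp = ramp_fit,
    jump = list(rates = jump_rates, steps = do.call(rbind, jump_steps)),
    high_force_fit = high_fit,
    landscape = landscape,
    pu_fit = if (inherits(pu_fit, "try-error")) NULL else pu_fit)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    dw_all <- do.call(rbind, dwell_tables)
    utils::write.table(dw_all, file.path(config$output_dir, "dwells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(force_pN = ruptures$forces),
      file.path(config$output_dir, "ruptures.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(config$output_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(c(
      sprintf("construct: %s", config$construct),
      sprintf("seed: %d", seed),
      sprintf("package: mtfold %s",
              as.character(utils::packageVersion("mtfold"))),
      sprintf("dwells: %d, ruptures: %d, jump events: %d",
              nrow(dw_all), length(ruptures$forces),
              sum(jump_rates$n_events))),
      file.path(config$output_dir, "run_log.txt"))
  }
  structure(report, class = "pipeline_report")
}

bell_to_json <- function(b) {
  list(k0 = b$k0, x = b$x, sign = b$sign, k0_err = b$k0_err,
       x_err = b$x_err, n_events = b$n_events)
}

report_to_json <- function(report) {
  list(
    construct = report$config$construct,
    seed = report$config$seed,
    equilibrium = report$equilibrium,
    fits = list(
      low_force_unfolding = bell_to_json(report$low_force_fits$unfolding),
      folding = bell_to_json(report$low_force_fits$folding),
      high_force_unfolding = bell_to_json(report$high_force_fit),
      ramp = c(bell_to_json(report$ramp$params),
               list(most_probable_force = report$ramp$most_probable_force,
                    loading_rate = report$ramp$loading_rate))),
    jump_steps = report$jump$steps,
    landscape = list(positions = as.list(report$landscape$positions),
                     energies = as.list(report$landscape$energies),
                     delta_g0 = report$landscape$delta_g0,
                     critical_force = report$landscape$critical_force))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report for %s (seed %d)\n",
              x$config$construct, x$config$seed))
  cat("  low-force unfolding: "); print(x$low_force_fits$unfolding)
  cat("  folding:             "); print(x$low_force_fits$folding)
  cat("  high-force unfolding:"); print(x$high_force_fit)
  cat(sprintf("  ramp: F* = %.2f pN from %d events\n",
              x$ramp$most_probable_force, x$ramp$n_events))
  print(x$landscape)
  invisible(x)
}
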