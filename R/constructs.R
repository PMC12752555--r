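# Per-construct physical models: dual-regime Bell unfolding laws, a folding
# law, elasticity, and the attempt rate used for barrier heights.

# Published two-state fit parameters for the cold-shock-protein constructs.
# ramp_*: single-Bell fit of the 1 pN/s rupture-force distribution.
# ku2/xu2: low-force (<= 8 pN) unfolding regime; xu1: high-force (>= 10 pN)
# transition distance.  dg0: zero-force folding free energy (k_BT) from
# constant-force unfolding probabilities.  The "native" construct behaves
# kinetically like LE-CSP-GS but releases only the 66 core residues.
.csp_presets <- list(
  "LE-CSP-GS" = list(ramp_k0 = 2.4e-2, ramp_x = 0.7, ku2_0 = 3.0e-2,
                     xu2 = 0.9, xu1 = 0.6, dg0 = 8.9, n_released = 70),
  "KL-CSP-GS" = list(ramp_k0 = 1.2e-2, ramp_x = 0.6, ku2_0 = 4.9e-3,
                     xu2 = 1.4, xu1 = 0.5, dg0 = 12.4, n_released = 70),
  "KL-CSP-LE" = list(ramp_k0 = 1.2e-2, ramp_x = 0.9, ku2_0 = 2.2e-3,
                     xu2 = 1.7, xu1 = 0.5, dg0 = 13.6, n_released = 70),
  "native"    = list(ramp_k0 = 2.4e-2, ramp_x = 0.7, ku2_0 = 3.0e-2,
                     xu2 = 0.9, xu1 = 0.6, dg0 = 8.9, n_released = 66)
)

#' Names of the built-in protein constructs
#' @return Character vector of construct identifiers.
#' @export
csp_constructs <- function() names(.csp_presets)

#' Assemble a construct model from explicit rate laws
#'
#' A construct model collects everything the simulator and the landscape
#' reconstruction need: the low-force and high-force Bell unfolding branches
#' (the true unfolding rate is the pointwise minimum of the two, so each
#' branch is exact on its own side of the regime boundary), the folding
#' branch, the elasticity parameters, and the attempt rate.
#'
#' @param construct_id Label for the construct.
#' @param low_force,high_force [bell_params()] unfolding branches dominating
#'   below/above `regime_boundary`.
#' @param folding [bell_params()] folding branch (`sign = -1`).
#' @param elasticity An [elasticity_params()] object.
#' @param ramp_fit Optional [bell_params()]: effective single-Bell parameters
#'   of the rupture-force distribution at 1 pN/s.
#' @param attempt_rate Intrinsic attempt rate k*, 1/s.
#' @param regime_boundary Force separating the two unfolding regimes, pN.
#' @return An object of class `construct_model`.
#' @export
construct_model <- function(construct_id, low_force, high_force, folding,
                            elasticity = elasticity_params(),
                            ramp_fit = NULL, attempt_rate = 1e6,
                            regime_boundary = 10) {
  stopifnot(inherits(low_force, "bell_params"),
            inherits(high_force, "bell_params"),
            inherits(folding, "bell_params"),
            inherits(elasticity, "elasticity_params"))
  if (low_force$sign != 1L || high_force$sign != 1L || folding$sign != -1L) {
    stop_invalid("unfolding branches must have sign +1, folding sign -1")
  }
  if (attempt_rate < max(low_force$k0, high_force$k0)) {
    stop_invalid("attempt_rate must be >= every fitted k0")
  }
  structure(list(
    construct_id = construct_id,
    low_force = low_force,
    high_force = high_force,
    folding = folding,
    elasticity = elasticity,
    ramp_fit = ramp_fit,
    attempt_rate = attempt_rate,
    regime_boundary = regime_boundary
  ), class = "construct_model")
}

#' Built-in cold-shock-protein construct models
#'
#' Returns the construct model for one of the published constructs. The two
#' printed unfolding branches are taken as-is; the high-force intercept
#' k_u1_0 (not printed) is set by continuity of the branches at the 10 pN
#' regime boundary, and the folding branch is anchored so that the rate
#' crossing falls at the coexistence force implied by the construct's
#' zero-force folding free energy through the chain-stretching energy
#' (G_stretch(f_c) = dG0).
#'
#' @param construct_id One of [csp_constructs()].
#' @param elasticity Optional [elasticity_params()]; defaults to the
#'   construct's released-residue count with standard chain constants.
#' @param folding_distance Folding transition distance x_f, nm.
#' @param attempt_rate Intrinsic attempt rate, 1/s.
#' @param regime_boundary Regime boundary, pN.
#' @return A [construct_model()] with extra fields `delta_g0_ref` (the
#'   anchoring folding free energy, k_BT) and `critical_force_ref` (pN).
#' @examples
#' m <- csp_construct("LE-CSP-GS")
#' unfolding_rate(m, 7)
#' @export
csp_construct <- function(construct_id = csp_constructs(),
                          elasticity = NULL, folding_distance = 5,
                          attempt_rate = 1e6, regime_boundary = 10) {
  construct_id <- match.arg(construct_id)
  p <- .csp_presets[[construct_id]]
  if (is.null(elasticity)) {
    elasticity <- elasticity_params(n_released_residues = p$n_released)
  }
  beta <- elasticity$thermal_energy
  ku1_0 <- p$ku2_0 * exp(regime_boundary * (p$xu2 - p$xu1) / beta)
  f_c <- invert_stretch_energy(p$dg0, elasticity)
  # anchor folding branch: k_f(f_c) = k_u(f_c) on the low-force branch
  ku_fc <- p$ku2_0 * exp(f_c * p$xu2 / beta)
  kf0 <- ku_fc * exp(f_c * folding_distance / beta)
  m <- construct_model(
    construct_id = construct_id,
    low_force = bell_params(p$ku2_0, p$xu2, 1L),
    high_force = bell_params(ku1_0, p$xu1, 1L),
    folding = bell_params(kf0, folding_distance, -1L),
    elasticity = elasticity,
    ramp_fit = bell_params(p$ramp_k0, p$ramp_x, 1L),
    attempt_rate = attempt_rate,
    regime_boundary = regime_boundary
  )
  m$delta_g0_ref <- p$dg0
  m$critical_force_ref <- f_c
  m
}

#' @export
print.construct_model <- function(x, ...) {
  cat(sprintf("Construct model: %s\n", x$construct_id))
  cat(sprintf("  low-force unfolding:  k0 = %.3g 1/s, x = %.3g nm\n",
              x$low_force$k0, x$low_force$x))
  cat(sprintf("  high-force unfolding: k0 = %.3g 1/s, x = %.3g nm\n",
              x$high_force$k0, x$high_force$x))
  cat(sprintf("  folding:              k0 = %.3g 1/s, x = %.3g nm\n",
              x$folding$k0, x$folding$x))
  if (!is.null(x$delta_g0_ref)) {
    cat(sprintf("  dG0 = %.3g k_BT (f_c = %.3g pN), k* = %.1g 1/s\n",
                x$delta_g0_ref, x$critical_force_ref, x$attempt_rate))
  }
  invisible(x)
}

#' Unfolding rate of a construct at a force
#'
#' The pointwise minimum of the two Bell branches: below the regime boundary
#' the low-force (shallow-barrier, larger transition distance) branch is the
#' slower of the two and limits the rate, above it the high-force branch
#' does, matching sequential-barrier kinetics.
#'
#' @param model A [construct_model()].
#' @param force Force, pN (vectorized).
#' @return Rate in 1/s.
#' @export
unfolding_rate <- function(model, force) {
  stopifnot(inherits(model, "construct_model"))
  beta <- model$elasticity$thermal_energy
  pmin(bell_rate(force, model$low_force, beta),
       bell_rate(force, model$high_force, beta))
}

#' Folding rate of a construct at a force
#'
#' @inheritParams unfolding_rate
#' @return Rate in 1/s.
#' @export
folding_rate <- function(model, force) {
  stopifnot(inherits(model, "construct_model"))
  bell_rate(force, model$folding, model$elasticity$thermal_energy)
}
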