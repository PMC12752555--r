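# Zero-force free-energy landscape reconstruction along the N-to-C terminal
# distance coordinate: positions of N, TS1, TS2, the barrier energies from
# zero-force rate constants, and the folding free energy dG0 by two routes
# (unfolding-probability fit, and coexistence work from the rate crossing).

#' Transition-state positions along the N-C distance coordinate
#'
#' The N-C distance of each transition state is the native N-C distance plus
#' the transition distance of the corresponding Bell branch: TS1 (high-force
#' barrier) uses x_u1, TS2 (low-force barrier) uses x_u2.
#'
#' @param model A [construct_model()].
#' @return Named numeric vector (nm): `N`, `TS1`, `TS2`.
#' @examples
#' transition_state_positions(csp_construct("LE-CSP-GS"))
#' @export
transition_state_positions <- function(model) {
  stopifnot(inherits(model, "construct_model"))
  nc <- model$elasticity$nc_distance_native
  c(N = nc, TS1 = nc + model$high_force$x, TS2 = nc + model$low_force$x)
}

#' Stationary-point energies of the zero-force landscape
#'
#' With the unfolded state U as the zero reference, the native state sits at
#' -dG0 and each transition state at -dG0 + dG*, where the barrier height
#' dG* = k_BT log(k*/k_u0) comes from the zero-force intercept of the
#' corresponding Bell branch and the attempt rate k*.
#'
#' @param model A [construct_model()].
#' @param delta_g0 Folding free energy, k_BT. Defaults to the coexistence
#'   value [delta_g0_from_rates()] computed from the model's own rate laws.
#' @return Named numeric vector (k_BT): `N`, `TS1`, `TS2`, `U`.
#' @export
landscape_energies <- function(model, delta_g0 = NULL) {
  stopifnot(inherits(model, "construct_model"))
  if (is.null(delta_g0)) {
    delta_g0 <- delta_g0_from_rates(model$low_force, model$folding,
                                    model$elasticity)
  }
  e_n <- -delta_g0
  c(N = e_n,
    TS1 = e_n + barrier_height(model$high_force$k0, model$attempt_rate),
    TS2 = e_n + barrier_height(model$low_force$k0, model$attempt_rate),
    U = 0)
}

#' Fit the force-dependent unfolding probability
#'
#' One-parameter least-squares fit of
#' P_u(f) = 1 / (1 + exp(dG0 - G_stretch(f))) (energies in k_BT), where
#' G_stretch is the chain-stretching free energy from the elasticity model.
#' The critical force solves G_stretch(f_c) = dG0, so the fitted curve has
#' P_u(f_c) = 1/2 by construction.
#'
#' @param force Forces, pN (>= 4 values spanning the transition).
#' @param pu Measured unfolding probabilities in \[0, 1\].
#' @param elasticity An [elasticity_params()] object.
#' @return List of class `pu_fit`: `delta_g0` (k_BT), `critical_force` (pN),
#'   `fitted` (P_u at the input forces), `rss`.
#' @export
fit_unfolding_probability <- function(force, pu,
                                      elasticity = elasticity_params()) {
  stopifnot(length(force) == length(pu))
  if (length(force) < 4) {
    stop_invalid("fit_unfolding_probability needs >= 4 forces")
  }
  if (all(pu < 0.02) || all(pu > 0.98)) {
    stop_invalid("unfolding probabilities do not span the transition; ",
                 "dG0 is unidentifiable")
  }
  gs <- stretch_free_energy(force, elasticity)
  model_pu <- function(dg0) 1 / (1 + exp(dg0 - gs))
  opt <- stats::optimize(function(dg0) sum((pu - model_pu(dg0))^2),
                         interval = c(0, max(gs) + 15))
  dg0 <- opt$minimum
  fc <- invert_stretch_energy(dg0, elasticity)
  structure(list(delta_g0 = dg0, critical_force = fc,
                 fitted = model_pu(dg0), rss = opt$objective),
            class = "pu_fit")
}

#' Folding free energy from the rate crossing
#'
#' Coexistence-work definition: the force f_c at which the unfolding and
#' folding Bell laws cross satisfies P_u = 1/2, and the folding free energy
#' equals the chain-stretching work at that force,
#' dG0 = G_stretch(f_c) (k_BT).
#'
#' @param unfold [bell_params()], unfolding branch (low-force regime).
#' @param fold [bell_params()], folding branch.
#' @param elasticity An [elasticity_params()] object.
#' @return dG0 in k_BT, with the crossing force as attribute
#'   `"critical_force"`.
#' @export
delta_g0_from_rates <- function(unfold, fold,
                                elasticity = elasticity_params()) {
  fc <- critical_force(unfold, fold, elasticity$thermal_energy)
  if (fc <= 0) {
    stop_invalid("rate laws have no crossing at positive force; ",
                 "dG0 undefined")
  }
  out <- stretch_free_energy(fc, elasticity)
  attr(out, "critical_force") <- fc
  out
}

#' Reconstruct the zero-force free-energy landscape of a construct
#'
#' Combines [transition_state_positions()], [delta_g0_from_rates()] and
#' [landscape_energies()] into the four stationary points reported along
#' the N-C distance coordinate. The unfolded reference is placed at the
#' root-mean-square end-to-end distance of the relaxed chain,
#' sqrt(2 L_p L_c).
#'
#' @param model A [construct_model()].
#' @param delta_g0 Optional folding free energy (k_BT); defaults to the rate
#'   crossing of the model's own laws.
#' @return Object of class `landscape_result`: `positions` (nm, named
#'   N/TS1/TS2/U), `energies` (k_BT, named, U = 0 reference), `delta_g0`,
#'   `critical_force` (pN), `construct_id`.
#' @export
reconstruct_landscape <- function(model, delta_g0 = NULL) {
  stopifnot(inherits(model, "construct_model"))
  if (is.null(delta_g0)) {
    delta_g0 <- delta_g0_from_rates(model$low_force, model$folding,
                                    model$elasticity)
  }
  fc <- attr(delta_g0, "critical_force") %||%
    critical_force(model$low_force, model$folding,
                   model$elasticity$thermal_energy)
  pos <- transition_state_positions(model)
  u_pos <- sqrt(2 * model$elasticity$persistence_length *
                  model$elasticity$contour_length)
  en <- landscape_energies(model, as.numeric(delta_g0))
  if (!(pos["N"] < pos["TS1"] && pos["TS1"] < pos["TS2"])) {
    stop_invalid("landscape positions are not ordered N < TS1 < TS2")
  }
  structure(list(positions = c(pos, U = unname(u_pos)),
                 energies = en,
                 delta_g0 = as.numeric(delta_g0),
                 critical_force = unname(fc),
                 construct_id = model$construct_id),
            class = "landscape_result")
}

#' @export
print.landscape_result <- function(x, ...) {
  cat(sprintf("Free-energy landscape (%s), U reference at 0:\n",
              x$construct_id))
  for (s in c("N", "TS1", "TS2", "U")) {
    cat(sprintf("  %-3s at %5.2f nm, %7.2f k_BT\n", s,
                x$positions[[s]], x$energies[[s]]))
  }
  cat(sprintf("  dG0 = %.2f k_BT, critical force = %.2f pN\n",
              x$delta_g0, x$critical_force))
  invisible(x)
}

#' Native N-C distance from a PDB structure
#'
#' Euclidean distance between the alpha-carbon atoms of the first and last
#' residues of a chain, in nm (PDB coordinates are Angstrom). For
#' multi-model (NMR) entries only the first model is read; alternate
#' locations other than 'A' or blank are skipped.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; defaults to the first chain encountered.
#' @return Distance in nm.
#' @export
nc_distance_from_structure <- function(path, chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1L)]
  atom <- lines[grepl("^ATOM", lines)]
  if (length(atom) == 0) stop_invalid("no ATOM records in ", path)
  name <- trimws(substr(atom, 13, 16))
  altloc <- substr(atom, 17, 17)
  ca <- atom[name == "CA" & altloc %in% c(" ", "A", "")]
  if (length(ca) == 0) stop_invalid("no alpha-carbon atoms in ", path)
  chains <- substr(ca, 22, 22)
  if (is.null(chain)) chain <- chains[1]
  ca <- ca[chains == chain]
  if (length(ca) < 2) {
    stop_invalid("chain '", chain, "' has fewer than two alpha-carbons ",
                 "(missing terminal CA)")
  }
  resno <- as.integer(substr(ca, 23, 26))
  coords <- cbind(as.numeric(substr(ca, 31, 38)),
                  as.numeric(substr(ca, 39, 46)),
                  as.numeric(substr(ca, 47, 54)))
  first <- which.min(resno)
  last <- which.max(resno)
  if (resno[first] == resno[last]) {
    stop_invalid("chain '", chain, "' contains a single residue")
  }
  sqrt(sum((coords[first, ] - coords[last, ])^2)) / 10
}
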