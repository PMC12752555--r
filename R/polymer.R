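# Polymer elasticity: worm-like chain for the unfolded peptide, a single
# freely-jointed (rigid Langevin) segment for the folded domain, the
# force-dependent unfolding step size, and the stretching free energy.

#' Elasticity parameters for a tethered two-state protein construct
#'
#' Bundles the polymer-elasticity constants used throughout the package: the
#' unfolded peptide is modelled as a worm-like chain (WLC) whose contour
#' length is the number of residues released upon unfolding times the contour
#' gain per residue, and the folded domain as a single freely-jointed-chain
#' (FJC) segment whose Kuhn length defaults to the native N-to-C terminal
#' distance.
#'
#' @param persistence_length WLC persistence length of the unfolded chain, nm.
#' @param contour_per_residue Contour length gained per released residue, nm.
#' @param n_released_residues Number of residues that gain chain contour upon
#'   unfolding (66 for the bare cold-shock domain, 70 with two appended
#'   residues at each terminus).
#' @param nc_distance_native Native-state distance between the terminal
#'   alpha-carbons, nm.
#' @param kuhn_length_native Kuhn length of the single FJC segment that stands
#'   in for the folded domain, nm. Defaults to `nc_distance_native`.
#' @param thermal_energy Thermal energy k_BT, pN nm.
#'
#' @return An object of class `elasticity_params`.
#' @examples
#' ep <- elasticity_params()
#' ep$contour_length # 70 * 0.38 = 26.6 nm
#' @export
elasticity_params <- function(persistence_length = 0.8,
                              contour_per_residue = 0.38,
                              n_released_residues = 70,
                              nc_distance_native = 1.3,
                              kuhn_length_native = nc_distance_native,
                              thermal_energy = 4.1) {
  check_scalar_positive(persistence_length, "persistence_length")
  check_scalar_positive(contour_per_residue, "contour_per_residue")
  check_scalar_positive(nc_distance_native, "nc_distance_native")
  check_scalar_positive(kuhn_length_native, "kuhn_length_native")
  check_scalar_positive(thermal_energy, "thermal_energy")
  if (!is.numeric(n_released_residues) || length(n_released_residues) != 1L ||
      n_released_residues < 1) {
    stop_invalid("`n_released_residues` must be >= 1")
  }
  contour_length <- n_released_residues * contour_per_residue
  if (contour_length <= nc_distance_native) {
    stop_invalid("released contour length (", contour_length,
                 " nm) must exceed the native N-C distance (",
                 nc_distance_native, " nm)")
  }
  structure(list(
    persistence_length = persistence_length,
    contour_per_residue = contour_per_residue,
    n_released_residues = n_released_residues,
    contour_length = contour_length,
    nc_distance_native = nc_distance_native,
    kuhn_length_native = kuhn_length_native,
    thermal_energy = thermal_energy
  ), class = "elasticity_params")
}

#' @export
print.elasticity_params <- function(x, ...) {
  cat("Elasticity parameters\n")
  cat(sprintf("  WLC: L_p = %.3g nm, L_c = %.3g nm (%d res x %.3g nm)\n",
              x$persistence_length, x$contour_length,
              as.integer(x$n_released_residues), x$contour_per_residue))
  cat(sprintf("  FJC (native): b = %.3g nm; N-C distance = %.3g nm\n",
              x$kuhn_length_native, x$nc_distance_native))
  cat(sprintf("  k_BT = %.3g pN nm\n", x$thermal_energy))
  invisible(x)
}

#' Marko-Siggia worm-like-chain force law
#'
#' Interpolation formula for the force required to hold a WLC at relative
#' extension z/L_c: f = (k_BT/L_p) * (1/(4 (1 - z/Lc)^2) - 1/4 + z/Lc).
#'
#' @param extension Extension z, nm (0 <= z < contour_length).
#' @param contour_length Contour length, nm.
#' @param persistence_length Persistence length, nm.
#' @param thermal_energy k_BT, pN nm.
#' @return Force in pN (vectorized over `extension`).
#' @export
marko_siggia_force <- function(extension, contour_length, persistence_length,
                               thermal_energy = 4.1) {
  check_scalar_positive(contour_length, "contour_length")
  check_scalar_positive(persistence_length, "persistence_length")
  z <- extension / contour_length
  if (any(z < 0) || any(z >= 1)) {
    stop_invalid("extension must lie in [0, contour_length)")
  }
  (thermal_energy / persistence_length) * (0.25 / (1 - z)^2 - 0.25 + z)
}

#' Worm-like-chain extension at a given force
#'
#' Inverts the Marko-Siggia force law by bracketed root finding on
#' z in [0, contour_length), so that plugging the returned extension back into
#' [marko_siggia_force()] recovers the input force to high precision.
#'
#' @param force Applied force, pN (vectorized, >= 0).
#' @param contour_length Contour length of the unfolded chain, nm.
#' @param persistence_length Persistence length, nm.
#' @param thermal_energy k_BT, pN nm.
#' @return Extension in nm; 0 at zero force, approaching the contour length
#'   from below at large force, strictly increasing in force.
#' @examples
#' wlc_extension(11.8, 26.6, 0.8) # ~ 0.64 * 26.6
#' @export
wlc_extension <- function(force, contour_length, persistence_length,
                          thermal_energy = 4.1) {
  check_nonnegative_force(force)
  check_scalar_positive(contour_length, "contour_length")
  check_scalar_positive(persistence_length, "persistence_length")
  check_scalar_positive(thermal_energy, "thermal_energy")
  one <- function(f) {
    if (f == 0) return(0)
    g <- function(z) marko_siggia_force(z, contour_length, persistence_length,
                                        thermal_energy) - f
    upper <- contour_length * (1 - 1e-12)
    if (g(upper) < 0) return(upper)
    stats::uniroot(g, lower = 0, upper = upper, tol = 1e-12)$root
  }
  vapply(force, one, numeric(1))
}

#' Freely-jointed-chain (Langevin) extension of the folded domain
#'
#' The folded protein is treated as a single rigid segment of length b whose
#' orientation equilibrates in the force field, giving the Langevin function
#' extension L * (coth(f b / k_BT) - k_BT / (f b)) with L = b.
#'
#' @param force Applied force, pN (vectorized, >= 0).
#' @param segment_length Kuhn/segment length b, nm (also the total length).
#' @param thermal_energy k_BT, pN nm.
#' @return Extension in nm; 0 at zero force, approaching `segment_length` at
#'   large force.
#' @examples
#' fjc_extension(11.8, 1.3) # ~ 0.95 nm
#' @export
fjc_extension <- function(force, segment_length, thermal_energy = 4.1) {
  check_nonnegative_force(force)
  check_scalar_positive(segment_length, "segment_length")
  check_scalar_positive(thermal_energy, "thermal_energy")
  u <- force * segment_length / thermal_energy
  out <- numeric(length(u))
  small <- u < 1e-4
  # series for u -> 0 avoids catastrophic cancellation: L(u) = u/3 - u^3/45
  out[small] <- segment_length * (u[small] / 3 - u[small]^3 / 45)
  ub <- u[!small]
  out[!small] <- segment_length * (1 / tanh(ub) - 1 / ub)
  out
}

#' Force-dependent unfolding step size
#'
#' The bead-height step observed upon unfolding at force f: the WLC extension
#' of the released contour minus the FJC extension of the native segment,
#' delta_x(f) = x_chain(f) - x_native(f).
#'
#' @param force Applied force, pN (vectorized, >= 0).
#' @param params An [elasticity_params()] object.
#' @return Step size in nm (0 at zero force, increasing with force).
#' @examples
#' step_size(11.8, elasticity_params()) # ~ 16 nm
#' @export
step_size <- function(force, params = elasticity_params()) {
  stopifnot(inherits(params, "elasticity_params"))
  wlc_extension(force, params$contour_length, params$persistence_length,
                params$thermal_energy) -
    fjc_extension(force, params$kuhn_length_native, params$thermal_energy)
}

# Fast interpolated step-size function on [0, fmax]; used by the simulators
# where step_size(f) is evaluated per sample.  Grid spacing keeps the
# interpolation error far below measurement noise (< 1e-3 nm).
step_size_fun <- function(params, fmax = 60, n_grid = 1200L) {
  grid <- seq(0, fmax, length.out = n_grid)
  stats::approxfun(grid, step_size(grid, params), rule = 2)
}

#' Stretching free energy of the released chain
#'
#' Reversible work to move the construct from the folded to the unfolded
#' branch while holding force f, computed as the integral of the step size
#' over force from 0 to f (adaptive quadrature), in units of k_BT.  This is
#' the quantity that balances the zero-force folding free energy at the
#' coexistence (critical) force.
#'
#' @param force Force, pN (vectorized, >= 0).
#' @param params An [elasticity_params()] object.
#' @return Energy in k_BT units; 0 at f = 0, strictly increasing.
#' @export
stretch_free_energy <- function(force, params = elasticity_params()) {
  stopifnot(inherits(params, "elasticity_params"))
  check_nonnegative_force(force)
  one <- function(f) {
    if (f == 0) return(0)
    q <- stats::integrate(function(x) step_size(x, params), 0, f,
                          rel.tol = 1e-8, subdivisions = 400L)
    if (q$message != "OK") {
      stop_invalid("quadrature failed for stretch_free_energy at f = ", f,
                   " pN: ", q$message)
    }
    q$value / params$thermal_energy
  }
  vapply(force, one, numeric(1))
}

# Force at which the stretching free energy equals `energy_kbt` (inverse of
# stretch_free_energy); internal, used to place the coexistence force of a
# construct at a stated folding free energy.
invert_stretch_energy <- function(energy_kbt, params, upper = 60) {
  stopifnot(energy_kbt > 0)
  stats::uniroot(function(f) stretch_free_energy(f, params) - energy_kbt,
                 lower = 1e-3, upper = upper, tol = 1e-9)$root
}
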