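# Construct-model factories for tests.

# Single-Bell-branch construct (both unfolding regimes identical), so the
# ramp rupture distribution is exactly Evans-Ritchie with these parameters.
make_simple_model <- function(ku0 = 2.4e-2, xu = 0.7, kf0 = 100, xf = 5,
                              n_released = 70) {
  construct_model(
    construct_id = "simple",
    low_force = bell_params(ku0, xu, 1L),
    high_force = bell_params(ku0, xu, 1L),
    folding = bell_params(kf0, xf, -1L),
    elasticity = elasticity_params(n_released_residues = n_released),
    attempt_rate = 1e6)
}

# Force-independent rates (Bell with negligible transition distance): a
# plain telegraph process, handy for occupancy and dwell statistics.
make_flat_model <- function(ku = 0.1, kf = 0.1) {
  construct_model(
    construct_id = "flat",
    low_force = bell_params(ku, 1e-9, 1L),
    high_force = bell_params(ku, 1e-9, 1L),
    folding = bell_params(kf, 1e-9, -1L),
    elasticity = elasticity_params(),
    attempt_rate = 1e6)
}

# Synthetic PDB text: CA-only chain with given CA coordinates (Angstrom).
synthetic_pdb <- function(coords, chain = "A", model_no = NULL) {
  lines <- character(0)
  if (!is.null(model_no)) lines <- c(lines, sprintf("MODEL     %4d", model_no))
  for (i in seq_len(nrow(coords))) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, chain, i, coords[i, 1], coords[i, 2], coords[i, 3]))
  }
  if (!is.null(model_no)) lines <- c(lines, "ENDMDL")
  c(lines, "END")
}
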