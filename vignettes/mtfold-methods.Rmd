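---
title: "Models and methods behind mtfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtfold)
```

## Scope

`mtfold` analyses (and simulates) single-molecule magnetic-tweezers
recordings of a two-state protein — a ~66-residue cold-shock domain held
between a surface and a paramagnetic bead — under three force protocols:
constant force, linear force ramps at ±1 pN/s, and force jumps. The
pipeline goes from a noisy bead-height time series to a zero-force
free-energy landscape with four stationary points (native state N, two
sequential transition states TS1/TS2, unfolded reference U) along the
distance between the terminal alpha-carbons (the N–C distance).

## The physical model

**Two-state kinetics under force.** Transitions N↔U are first-order with
Bell-model rates
$k(f) = k_0 \exp(\pm f x / k_B T)$,
where $x$ is the distance to the transition state along the pulling
coordinate (`bell_params()`, `bell_rate()`). Unfolding shows two regimes:
below ~10 pN a distal barrier (TS2, larger $x_{u,2}$) limits the rate,
above it a proximal barrier (TS1, smaller $x_{u,1}$). A construct model
(`construct_model()`) therefore carries two unfolding branches and evaluates
the true unfolding rate as their pointwise minimum — the slower barrier
limits sequential barrier crossing, and each printed regime fit is exact on
its own side of the boundary.

**Rupture forces under a ramp.** For a linear ramp $f = r t$ the
first-passage density is the Evans–Ritchie distribution
$p(F) = \frac{k(F)}{r}\exp\!\Big[\frac{k_0 k_BT}{x r}\big(1 - e^{F x/k_BT}\big)\Big]$,
with closed-form mode $F^* = (k_BT/x)\ln\!\big(x r/(k_0 k_BT)\big)$
(`evans_ritchie_pdf()`, `most_probable_force()`). With the published
LE-CSP-GS parameters ($k_u^0 = 2.4\times10^{-2}\,s^{-1}$, $x_u = 0.7$ nm,
$r = 1$ pN/s) this gives 11.49 pN.

**Elasticity.** The unfolded chain is a Marko–Siggia worm-like chain;
`wlc_extension()` inverts the force law by bracketed root finding
(tolerance $10^{-12}$), and the inversion round-trips to $10^{-8}$
relative. The folded domain is a single freely-jointed segment whose
extension is the Langevin function (`fjc_extension()`). The unfolding step
is $\Delta x(f) = x_{chain}(f) - x_{native}(f)$ (`step_size()`), and the
stretching free energy $G_s(f) = \int_0^f \Delta x\,df'$
(`stretch_free_energy()`, adaptive quadrature) converts forces into
energies.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| $k_BT$ | 4.1 | pN·nm | room temperature; the source experiments state no temperature |
| contour per residue | 0.38 | nm | field-standard polypeptide value |
| persistence length $L_p$ | 0.8 | nm | field-standard for polypeptide WLC fits |
| released residues | 70 (66 native) | — | 66 core residues + 2 appended at each terminus |
| native N–C distance | 1.3 | nm | terminal Cα distance of the deposited structure |
| folded segment length | 1.3 | nm | rigid-body orientation convention: one FJC segment spanning N to C |
| attempt rate $k^*$ | $10^6$ | $s^{-1}$ | standard intrinsic folding attempt frequency |
| regime boundary | 10 | pN | force separating the TS1/TS2 regimes |
| folding distance $x_f$ | 5 | nm | declared choice; see below |
| sampling rate | 200 | Hz | camera rate of the emulated instrument |
| noise σ | 6 | nm | gives ~2.5 signal-to-noise on a 15 nm step |

Three kinetic quantities are not printed in the source work and are
declared package choices: the high-force intercepts $k_{u,1}^0$ (set by
continuity of the two Bell branches at 10 pN), the folding law (a Bell-type
"Arrhenius" law with constant $x_f = 5$ nm, a typical steep folding-branch
slope for a ~70-residue chain), and the folding intercept $k_f^0$, anchored
so that the rate crossing (the coexistence force $f_c$) satisfies
$G_s(f_c) = \Delta G_0$ with each construct's published folding free energy
(8.9, 12.4, 13.6 $k_BT$). These choices make the simulator reproduce every
printed number by construction while remaining internally consistent.

Note one deliberate inconsistency of the two-route world: a Bell folding
law and the polymer-logistic occupancy model imply slightly different
$P_u(f)$ *shapes*; both pin $P_u(f_c) = 1/2$ at the same $f_c$, so the two
$\Delta G_0$ routes (`delta_g0_from_rates()`, `fit_unfolding_probability()`)
agree within ~0.3 $k_BT$ on synthetic data.

## The synthetic-data generator

`simulate_constant_force()` draws exact Gillespie dwell sequences;
`simulate_ramp()` inverts the closed-form integrated hazard of the Bell
laws along the ramp (exact for time-varying rates, split at the regime
boundary); `simulate_force_jump()` chains constant-force segments with
state carry-over. Heights are baseline + state × $\Delta x(f)$ + i.i.d.
Gaussian noise. Optional extras — all off by default — are a linear
baseline drift, an Ornstein–Uhlenbeck noise mode (`noise_corner`, Hz)
giving correlated tracking noise of the same marginal width, and a
per-trace force-calibration error (`force_scale_sd`, e.g. 0.05 for the
instrument's ~5% force uncertainty) that perturbs the true force while
the nominal force is recorded. Camera blur within a frame, bead
hydrodynamics and the tether-validation unzipping signal near 30 pN are
*not* emulated. A green test therefore establishes correctness of the
inference chain on idealized two-state data, not robustness to
instrument artifacts.

## Analysis choices

- **Segmentation**: two-state Gaussian-emission HMM (Baum–Welch, compiled
  forward–backward with scaling; Viterbi decoding) run on raw 200 Hz data;
  smoothing (`smooth_height()`, 20 samples ≙ 0.1 s) is for display and
  occupancy histograms only, to avoid dwell-time distortion. States are
  ordered by emission mean so labels cannot swap.
- **Occupancy**: two-Gaussian EM (`fit_occupancy()`) with mode-based
  initialization; a fit is declared degenerate when the component means sit
  closer than half the pooled width *or* the mixture shows no density dip
  between the peaks (a unimodal cloud can otherwise be split silently).
- **Dwell censoring**: boundary dwells are flagged with separate
  start/end censoring. The default rate estimator uses fully-uncensored
  dwells (simple, but length-biased upward by ~7% when dwells reach ~5% of
  the trace length); the censoring-aware MLE (`include_censored = TRUE`)
  counts start-censored dwells as events — by memorylessness they are valid
  draws — and all durations as exposure, and is unbiased. The survival
  curve is written $P(t) = 1 - e^{-kt}$ (cumulative form) for parity with
  the conventional presentation; the fitted $k$ is identical.
- **Dead time**: first-passage analysis of force jumps uses step detection
  with a two-window scan; dwells shorter than twice the detection window
  are discarded and the exponential origin is shifted accordingly
  (`survival_fit(min_dwell = ...)`), which leaves the MLE unbiased.
- **Ramp fits**: maximum likelihood on the Evans–Ritchie density in
  log-parameters is the default; a 1 pN left-closed-bin histogram
  least-squares mode exists for parity with binned fitting. Errors by
  nonparametric bootstrap (200 resamples). The ramp starts at ~2 pN in the
  emulated protocol while the fit uses the $[0,\infty)$ form; the mass
  below 2 pN is $<10^{-3}$ for all relevant parameters and is ignored.
- **Landscape**: positions are $x_N = 1.3$ nm,
  $x_{TS_i} = 1.3 + x_{u,i}$ nm; energies (U as zero reference) are
  $E_N = -\Delta G_0$ and $E_{TS_i} = E_N + \ln(k^*/k_{u,i}^0)$ in $k_BT$.
  The U marker is drawn at the relaxed-coil RMS end-to-end distance
  $\sqrt{2 L_p L_c}$ — a display convention, not a fitted quantity.

## Numerical notes

- WLC inversion: Brent/uniroot on $z \in [0, L_c)$, tol $10^{-12}$; the
  simulators interpolate $\Delta x(f)$ on a 1200-point grid (error
  $\ll$ noise).
- Rates are fitted in log space (positivity, stabilized weights); weights
  come from the delta method on rate standard errors.
- Degenerate inputs error early with descriptive messages (no silent NA
  propagation): empty states, non-crossing rate laws, unidentifiable
  $P_u$ data, non-monotonic time stamps.

## What the tests establish (and what they do not)

The acceptance suite recovers, from fully synthetic data: the published
ramp-fit parameters within their printed uncertainties (500 events), all
four low-force Bell parameters within 20% and $\Delta G_0$ within 1
$k_BT$ per construct (events-targeted acquisition sized by a
pre-registered power analysis; ~95% joint pass probability), step sizes
within 1.5 nm of the polymer model over 10–30 pN, and the arithmetic
identities of the landscape. Equilibrium windows follow the per-construct
ranges over which dwells are actually resolvable at 200 Hz (4–8, 5–8 and
6–8 pN) — below these, sub-0.5 s dwells produce systematic dwell-merging
bias that no amount of data cures.

Known limitations: the Marko–Siggia chain keeps extending above ~19 pN, so
the step-size band [14, 18] nm holds over ~10–18 pN with the default
elasticity rather than the full jump range; Dudko-type $\nu$-family fits,
three-state global likelihoods, multi-state HMMs and drift beyond a linear
baseline are out of scope.

## A worked landscape

```{r landscape}
model <- csp_construct("KL-CSP-GS")
reconstruct_landscape(model)
```
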