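---
title: "Models and methods: dark-state trapping kinetics in chromophore anions"
author: "darktrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dark-state trapping kinetics in chromophore anions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darktrap)
```

# The system and the questions

The meta isomer of the GFP chromophore anion (meta-HBDI) has an
optically dark first excited singlet state S1 of charge-transfer
character lying below the bright, locally excited S2 state.  After
photoexcitation into S2, internal conversion funnels the population into
S1, where it is trapped behind a barrier on the pathway to the S1/S0
conical intersection.  Three experimental observables characterise this
mechanism, and this package implements the analysis behind each of them:

1. **Photodetachment channel energetics.**  Electron kinetic energies
   (eKE) in the 2D photoelectron spectrum follow simple level arithmetic
   over the electronic state diagram: direct detachment gives
   `eKE = hv - VDE(D0)`, detachment from a trapped excited state gives at
   most `eKE = AEE + hv - VDE(D0)`, and binding energies convert through
   `BE = hv - eKE`.
2. **Pump-probe transients.**  Prompt and delayed neutral yields as a
   function of pump-probe delay are described by a sequential three-state
   cascade S2 -> S1 -> S0 convolved with a Gaussian instrument response.
3. **Statistical (RRKM/quasi-equilibrium) lifetime.**  The trapped S1
   population decays over the barrier with the microcanonical rate
   `k(E) = sigma W'(E - E0) / (h rho(E))`, thermally averaged over the
   stored-ion ensemble.

A fourth, auxiliary analysis determines the photon order of an action
signal from its laser-pulse-energy dependence (log-log slope 1 or 2).

Because the raw beamline data are not distributed with the package, a
seeded synthetic-data module generates every input the pipeline consumes,
with the statistical structure the analysis assumes.  All tests and the
acceptance script run entirely on these generators plus the packaged
level-diagram fixture.

# The level diagram and channel energetics

`read_level_diagram()` loads a JSON description of the electronic states
and detachment thresholds.  Every threshold carries a provenance tag —
`measured` (photoelectron spectroscopy) or `calculated` (multireference
perturbation theory) — because the two are routinely mixed when assigning
spectra: the measured VDE(D0) is 2.63 eV while the calculated value is
2.54 eV, and the published "~2.0 eV" two-photon arithmetic is consistent
with the calculated value.  Rather than silently preferring one, every
operation takes explicit energies and the accessors let the caller choose;
the default preference is `measured`, falling back to `calculated`.

```{r}
d <- read_level_diagram(system.file("extdata", "meta_hbdi_levels.json",
                                    package = "darktrap"))
d
```

Closed channels (non-positive eKE) return a *flagged* value rather than
raising, so that spectrum simulation can sweep all channels uniformly;
`is_open()` reads the flag.

`classify_channel()` maps a (photon energy, eKE) pixel to one of the five
mechanistic regions of the 2D photoelectron map: (i) the direct D0 ridge,
(ii) the direct D1n ridge, (iii) two-photon detachment via S1 above the
direct line, (iv) low-energy statistical electrons, and (v) the broadened
direct ridge inside the 3.6-3.9 eV S3 shape-resonance window.  Region
definitions overlap (the wing of a broadened ridge can satisfy the
two-photon condition; near-threshold D1n electrons have near-zero eKE), so
the classifier applies a fixed priority order **iii > i > ii > v > iv**.
Placing iii first is a deliberate design choice: two-photon electrons are
*defined* by exceeding the direct line, so that condition must win
wherever it holds.  The ridge tolerance (default 0.1 eV), low-eKE cutoff
(default 0.1 eV) and broadening tolerance (default 0.25 eV) are
configurable and should be matched to the experimental resolution.

# The sequential kinetic model

With unit population prepared in S2 at time zero and rate constants
`k1 = 1/tau_fast` (S2 -> S1) and `k2 = 1/tau_slow` (S1 -> S0):

$$P_{S2}(t) = e^{-k_1 t},\qquad
  P_{S1}(t) = \frac{k_1}{k_2 - k_1}\left(e^{-k_1 t} - e^{-k_2 t}\right),\qquad
  P_{S0}(t) = 1 - P_{S2} - P_{S1}.$$

The degenerate limit `k1 = k2` is handled analytically
(`P_S1 = k t e^{-kt}`) below a relative rate difference of 1e-9; the two
branches agree to better than 1e-7 across the switch-over.  Computing
`P_S0` by conservation makes the population sum exactly one in floating
point.

The finite pump-probe cross-correlation is modelled as a single Gaussian
of width `irf_sigma` (default 80 fs — the scale of a cross-correlation of
tens-of-fs pulses; the experiment quotes no number, so the width is a
parameter and can be fitted or fixed).  Convolution of each exponential
component has the closed exponentially-modified-Gaussian form

$$\frac{A}{2}\,
  \exp\!\left(\frac{\sigma^2}{2\tau^2} - \frac{t-t_0}{\tau}\right)
  \operatorname{erfc}\!\left(\frac{\sigma/\tau - (t-t_0)/\sigma}{\sqrt2}\right),$$

evaluated in log space (via the log of the normal tail) so that it stays
finite deep in the pre-pulse and tail regions.  The prompt channel is
`baseline + amp_s2 P_S2 + amp_s1 P_S1` (convolved); the delayed channel is
`baseline + amp_s0 P_S0`, i.e. pure ground-state recovery.  No attempt is
made to split the delayed yield into statistical-fragmentation and
thermionic-emission contributions: the experiment does not separate them
quantitatively, and both ride on `P_S0`.

## Fitting

`fit_transients()` minimises the weighted sum of squared residuals with
Levenberg-Marquardt (minpack.lm).  Whether the published analysis fitted
the two channels jointly or separately is not stated; this package fits
them *jointly* by default — the two channels share `tau_fast`, `tau_slow`,
`t0` and `irf_sigma`, each keeping its own amplitudes and constant
baseline — and fitting a single channel remains possible by omitting the
other.  A constant per-channel baseline is the default background model.

Numerical choices that matter:

* **Positivity by construction.**  Lifetimes and the IRF width are
  optimised as logarithms.
* **Multi-start on the fast lifetime.**  Multiexponential objectives have
  a well-known spurious minimum in which the fast component collapses
  below the delay sampling and its amplitude becomes unconstrained.  The
  fit is therefore restarted from several fast-lifetime initialisations
  (multipliers 1, 0.2, 5, 25 on the supplied guess) and the lowest
  deviance wins.  The collapsed solutions are visibly worse in
  chi-square, so the selection is unambiguous.
* **Canonical ordering.**  The two-exponential span is symmetric under
  relabelling, so after convergence the labels are reordered to
  `tau_fast <= tau_slow`, the amplitudes remapped to leave the curve
  unchanged, and the fit restarted once from the reordered optimum so the
  covariance refers to canonical labels.
* **Uncertainties** come from the Gauss-Newton covariance
  `redchi2 * (J'J)^-1` at the optimum, delta-transformed back from log
  space.  Non-convergence and degenerate (constant) data are flagged
  results, never silent answers.

# Quasi-equilibrium statistical lifetime

`count_states()` performs the exact Beyer-Swinehart direct count of
harmonic vibrational states on a 1 cm^-1 grid (the default; each mode
frequency is rounded to the nearest grid multiple).  Energies are
measured from the zero-point level, so `W(0) = 1`.  The density of
states is the per-bin count divided by the bin width, and the
microcanonical rate over a barrier `E0` is

$$k(E) = \frac{\sigma\, W^{\ddagger}(E - E_0)}{h\, \rho(E)},$$

with the symmetry factor `sigma = 1` by default (no degeneracy
information is available for this pathway).  The treatment is harmonic
only: no anharmonicity, no rotations, no tunnelling — there is no
evidence the original analysis included them, and the frequency data to
calibrate them are not available.

The stored-ion ensemble before excitation is Boltzmann-distributed over
the ground-state vibrational manifold,
`P(E) ~ rho_S0(E) exp(-E/kB T)`.  Whether the pre-excitation distribution
should use S0 or S1 frequencies is not specified in the source analysis;
S0 is the physically natural choice (the ions are cold in S0 when the
pump arrives) and is the default, with a separate `freqs_s0` argument to
override.  After absorbing a pump photon `hv`, each ensemble member
carries `E = Ev + hv - AEE(S1)` of vibrational energy in S1, and the
ensemble survival is the weighted mixture
`S(t) = sum P(Ev) exp(-k(E) t)`.

Because the mixture is non-exponential, "lifetime" needs a convention:
this package reports the **1/e crossing** of `S(t)`, located by linear
interpolation in `log S`.  (An initial-rate inverse would be an equally
defensible convention; the 1/e time is chosen because it is directly
testable against the analytic single- and two-component oracles.)

## What the synthetic frequencies do and do not show

The vibrational frequencies of the real molecule are not printed in the
available text, so `generate_frequency_set()` draws a 78-mode set
uniformly over 50-3500 cm^-1 — the mode count and span of a mid-size
organic chromophore — and builds the transition-state set by removing the
lowest mode (the reaction coordinate) and perturbing the rest by a seeded
±10%.  With the published 0.41 eV barrier, 300 K and 400 nm excitation,
this machinery yields lifetimes in the ps-ns regime that decrease
monotonically with temperature and with photon energy.  That is the
correct *order of magnitude* and the correct *trend*; the published 98 ps
value itself is not reproducible without the real frequencies and the
exact statistical convention of the original supplementary analysis, and
the package makes no claim to reproduce it.  The energy grid extends to
the pump energy plus a generous thermal margin, where the count is
converged: refining the bin from 2 to 1 cm^-1 moves `k(E)` by less than
1% at energies 0.1 eV or more above the barrier on dense manifolds (very
close to threshold, `W'` is a staircase of a handful of states and is
sensitive to how frequencies round onto the grid — rates there should be
treated qualitatively).

# Power-law photon order

`fit_power_exponent()` regresses `log(yield)` on `log(pulse energy)`;
the slope is the photon order.  Log-log regression is chosen over a
direct nonlinear fit for robustness at the few points a typical
power-dependence series contains; the two agree exactly on noiseless
data.  `classify_photon_order()` calls an exponent one- or two-photon
when it lies within `max(2 sigma_n, 0.15)` of the integer — the 0.15
floor prevents a sparse four-point series with an optimistically small
formal error from over-claiming.  `normalize_by_power()` divides yields
by `P^n`, the step used to put action spectra recorded at different pulse
energies on a common scale.

# Forward-simulated 2D spectra

`simulate_pe2d()` builds the intensity map additively from channel
specifications: Gaussian ridges (default width 0.15 eV, standing in for
the unmodelled experimental resolution and Franck-Condon envelope) at the
channel's energetic position, an exponential low-eKE tail, and an extra
wider ridge at the direct position inside the S3 window.  Closed channels
contribute nothing.  The map is normalised to unit maximum because
absolute electron counts are instrument-dependent; relative region
amplitudes are free configuration, not fitted quantities.
`generate_pe_counts()` overlays Poisson statistics for a requested total
count.  `spectral_cut()` and `peak_eke()` (three-point parabolic
interpolation, ties resolved to the lower-eKE peak) extract the 1D
observables.

# Synthetic data and reproducibility

Every generator is a pure function of its parameters and an integer seed.
Transients default to 5% multiplicative lognormal noise — the visual
scatter scale of typical ion-yield data; the experiment quotes no noise
figure.  Generators attach their ground-truth parameters to the returned
object (and CSV writers carry them in a reserved `#` comment header), so
recovery tests never re-derive truth from noisy data.

The study sizes used throughout the tests and the acceptance script are:
100 replicate transient pairs of 60 log/linear-spaced delays from -0.5 to
400 ps for the lifetime-recovery study; 50 random systems of up to 12
modes (compared against exhaustive enumeration below 2e5 states); and a
161 x 251 pixel 2D map for the classifier calibration.  These sizes give
stable medians and percentile statements while keeping a full run in the
minutes range on a single core.

# Known limitations

* Harmonic state counting only; no rotational or anharmonic corrections,
  no tunnelling through the barrier, no master-equation treatment of
  collisional relaxation, and no competition with vibrational
  autodetachment.
* The synthetic frequency sets reproduce scale and trends of the
  statistical lifetime, not its exact value.
* The D1 probe channel seen in the time-resolved experiment is not
  modelled: the underlying D1 energy is not available, and whether it
  coincides with the D1n level of the nanosecond-laser analysis cannot be
  resolved from the text.
* No photoelectron angular distributions and no autodetachment lineshape
  theory for the S2 Feshbach or S3 shape resonances; region (iv) is
  phenomenological.
* Rotamer-induced VDE broadening (~0.2 eV) is documented but not
  modelled.
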