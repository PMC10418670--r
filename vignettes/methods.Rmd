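---
title: "Methods: a self-consistent electron-scattering data set for 1M5NI and its track-structure simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-section assembly and track structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xs1m5ni)
```

## The data set and its closure rule

1-methyl-5-nitroimidazole (1M5NI, C₄H₅N₃O₂, 127 u, permanent dipole
4.4 D) is a candidate molecular radiosensitizer: low-energy electrons
dissociate it into reactive anions that damage DNA. Simulating that
chemistry needs channel-resolved integral cross-sections over the full
slowing-down range of secondary electrons, 0.1–1000 eV.

The package's central object, the `xs_set`, holds one energy-gridded
table per scattering channel in units of 10⁻²⁰ m² (= Å²). The defining
constraint is *closure*: at every energy the open channels — elastic,
electron attachment, vibrational excitation, electronic excitation,
ionization — must sum to the reference total cross-section (TCS). The
reference is a transmission-beam measurement corrected for the elastic
flux scattered into the detector's forward acceptance cone (the
"missing-angle" correction), extended above 300 eV by calculation.
`validate_consistency()` audits this closure on the reference grid and
reports per-energy discrepancies; the packaged recommended set closes
within 0.15 × 10⁻²⁰ m² everywhere except its 70 eV row, whose printed
channel entries (33.6 + 11.5 + 12.5 = 57.6) disagree with their own
printed sum (66.4). We treat that row as a registered anomaly — flagged
in the closure report, never silently corrected.

Rotational excitation is carried as a separate qualitative channel and is
deliberately *excluded* from closure sums: the reference TCS does not
resolve rotational transfers (0.617 meV thermal average, far below any
beam resolution), so adding the rotational cross-section to the sum would
double-count flux.

### Interpolation

Channel tables are evaluated off-grid by log–log linear interpolation:
cross-sections are positive, smooth, and span three decades in energy, so
linearity in (log E, log σ) is the natural local model and guarantees
interpolated values stay between the bracketing nodes. Grid hits return
the stored value bit-for-bit. Two deliberate deviations:

* where a bracketing value is zero (a channel switching on or off — blank
  cells in the source table are read as zero), the interpolation falls
  back to linear–linear, which handles the transition without taking
  `log(0)`;
* outside the tabulated span the library refuses to extrapolate and
  raises an error. The transport module inherits this: it will not track
  electrons outside 0.1–1000 eV.

A `method = "linear"` option forces linear–linear interpolation
throughout, for sub-eV resonant structure on coarse grids.

## Assembly operations

`missing_angle_correction()` integrates a user-supplied elastic DCS over
the acceptance cone, Δσ = 2π∫₀^θacc (dσ/dΩ) sinθ dθ (plus an optional
backward cone for magnetically confined beams), using adaptive quadrature
(`stats::integrate`, relative tolerance 10⁻¹⁰). Tests pin it against
closed forms for isotropic and cos²θ distributions to six figures.

`derive_total_inelastic()` subtracts the integral elastic table from the
reference TCS pointwise. Small negative differences are expected where
the elastic channel nearly exhausts the TCS (both inputs carry
measurement and rounding error); they are clamped to zero and logged via
a warning rather than rejected.

### Resonance extraction

At low energy, a fixed-nuclei elastic calculation produces the smooth
elastic cross-section *plus* sharp resonant structures (transient anion
states). `extract_resonances()` separates them without assuming a line
shape:

1. fit a smoothing spline (default 8 effective degrees of freedom)
   through the curve in log–log coordinates;
2. find *core* points lying more than `band = 2` residual spreads above
   the fit, with the spread estimate floored at 1% (log units) so that a
   noiseless curve cannot drive runaway clipping;
3. expand each core run outward to the residual's crossing of the
   background (−spread/2), so the peak's wings are excluded from the
   refit; the two outermost grid points on each side always remain, so
   the spline stays anchored at the edges;
4. refit on the surviving points and iterate (cap 20 passes).

The attachment cross-section is the non-negative excess of the curve over
the background, reported only inside detected peak runs — a strictly
smooth curve therefore yields an identically zero attachment, and
re-running the extraction on its own background output returns nothing
(idempotence). Peaks centred above the pseudo-resonance cutoff (default
10 eV, configurable) are flagged as artifacts of the missing inelastic
channels in the elastic calculation and removed from the attachment
curve.

On synthetic curves (smooth `a + b/E` background plus a Lorentzian at
2 eV) the extraction recovers the resonant area to better than 1% on a
90-point log grid and locates the centre exactly. Known limitations,
measured on the same synthetic family: on the coarse printed low-energy
grid the recovered area is biased low by ≈ 10% (the grid under-resolves
the peak), and ≈ 0.5% multiplicative noise biases the area low by
10–20% because the wing expansion stops at the first noise-induced
zero-crossing. The extraction is therefore quantitative on dense smooth
curves and semi-quantitative otherwise.

### Partitioning the inelastic residual

After removing ionization and attachment from the total inelastic
cross-section, the remainder must be split between vibrational and
electronic excitation. The source analysis anchors the two channels at
their thresholds and samples their magnitudes so the sum closes to the
reference; since no formula for that sampling is published, the package
represents the split explicitly as per-energy *anchor weights* w_e(E) —
the electronic fraction of the residual — interpolated in log E, forced
to zero below the electronic threshold, and calibrated from the printed
recommended tables by `calibrate_partition()`. The partition conserves
the residual exactly at every grid point by construction
(vibrational = residual − electronic). Rebuilding the vibrational and
electronic columns through the full chain (reference TCS → elastic
subtraction → minus ionization and attachment → partition) reproduces
the printed columns within 0.15 × 10⁻²⁰ m² except at 15, 200 and 300 eV,
where the printed reference TCS and the printed channel sum themselves
disagree by 0.16–0.42.

## The differential inelastic model

Double-differential inelastic cross-sections for a molecule of this size
are measured at isolated conditions only, so the package uses the
single-parameter semiempirical form

d²σ/dΩdΔE ∝ (dσ/dΩ)ₑₗ · (1 − k·ΔE/E),

the angular distribution of the elastic channel attenuated linearly in
the fractional energy transfer. The default weight k = 1.3 is the value
calibrated for 1M5NI from angular distributions measured at E = 97 eV,
ΔE = 30 eV, where the attenuation factor is 1 − 1.3·30/97 = 58/97. Where
k·ΔE > E the factor is clamped to zero (the linear form is silent
there). The stated proportionality is closed by normalizing the double
integral over solid angle and transferred-energy bins to the channel's
integral cross-section at that energy — the only choice consistent with
the closure rule above.

`estimate_k()` recovers k from angular data by weighted linear least
squares: the model is linear in (c, −ck), so intensity regresses on
`dcs` and `dcs·ΔE/E`, with k = −b/a and a delta-method standard error.
One subtlety is structural: with the overall scale free, data at a
*single* transferred energy cannot identify k (c and k enter only through
c(1 − kΔE/E); the regressors are exactly collinear, and ΔE = 0 is the
limiting case). The function therefore requires data spanning at least
two distinct ΔE values — e.g. intensities binned in energy loss around
the representative condition — and raises an explicit identifiability
error otherwise. On synthetic data at ΔE ∈ {15, 30, 45} eV with 5%
multiplicative noise, k is recovered within two standard errors;
noiseless data returns the generating k to six figures, and the estimate
is invariant under rescaling all intensities.

Angular sampling inverts the cumulative distribution of μ = cosθ
tabulated on a 513-point grid (piecewise-linear density); since the
attenuation factor is angle-independent, the angular profile at any
(E, ΔE) is that of the elastic DCS at E.

## Fragmentation statistics

**Anions (DEA).** Branching ratios are anchored at the two incident
energies with published numbers: 3.1 eV (NO₂⁻ 58%) and 4.7 eV (NO₂⁻ 35%,
CN⁻ 21%, CNO⁻ 10%). Probabilities are interpolated linearly between the
anchors and held at the nearest anchor outside the 3.1–4.7 eV window,
since no measurements exist elsewhere; transport can alternatively
disable DEA outside the resonance region by removing the channel. Three
package assumptions fill documented gaps:

* the five minor fragment channels (C₂N₂Hₓ⁻, C₃N₂Hₓ⁻, C₄N₂Hₓ⁻, NO loss,
  OH/CH₃ loss, each individually under 10%) share the residual
  probability equally;
* at 3.1 eV their combined share is set to 23% — the lower end of the
  reported 23–30% combined yield, consistent with the minor channels
  growing toward 4.7 eV — leaving 19% for CN⁻ + CNO⁻, split 21:10 in
  proportion to their reported maxima;
* fragment kinetic energies are exponential with species-specific means
  (CN⁻ 0.2 eV, all others 0.05 eV — configuration values, not
  measurements): a zero-mode decaying shape matching the observation
  that all KE distributions peak near 0 eV with CN⁻ distinctly broader,
  with isotropic emission matching the measured momentum images.

**Cations.** Relative intensities of the 18 cationic species observed at
67 eV impact (parent C₄H₅N₃O₂⁺ ≡ 1; strongest fragments CHO⁺ 0.768,
CH₃NO⁺ 0.633, C₂H₄N₂⁺ 0.571) drive a categorical sampler, invariant
under intensity rescaling. Treating these intensities as
energy-independent is a documented limitation — they were measured at a
single energy.

## Rotational excitation

The rigid-rotor first-Born point-dipole model reduces the full
rotational-level sum to one effective transition at the thermally
averaged transfer ΔE_rot = 0.617 meV (300 K): no rotational constants for
1M5NI are available, and ΔE_rot/E ≤ 6×10⁻³ across the working grid, so
quasi-elastic kinematics (K = 2k sin(θ/2)) apply. The DCS is
(4/3)D²(k_f/k_i)/K² in atomic units; its θ→0 divergence is regularized by
a minimum-transferred-energy cutoff (default ΔE_rot itself) translated
into a minimum angle via 2k sin(θ_c/2) = k − k′(ε_cut). The integral then
has the closed form (8π/3)(D²/k²)·ln(1/sin(θ_c/2)), which tests verify
against direct quadrature to six figures. The resulting integral
cross-section decreases monotonically over 0.1–1000 eV — the only
property asserted: absolute values from this crude model are qualitative,
which is exactly why the channel never enters closure sums.

## Track-structure transport

`simulate_tracks()` moves each electron in exponential free steps
s = −ln u / (n·σ_tot(E)), chooses the collision channel with probability
σ_ch(E)/σ_tot(E), and applies the channel semantics: elastic collisions
deflect without energy loss (recoil against a 127 u target is neglected,
a ≲ 10⁻⁴ relative error per collision); vibrational and electronic
collisions subtract their channel loss and deflect via the DDCS profile;
ionization spawns a secondary electron; attachment captures the electron
and samples an anion. Secondaries go on a stack and are transported
identically. Where the published analysis stops at the cross-sections,
transport conventions are package choices, all config-exposed and
provenance-flagged:

* **ionization energy** 9.0 eV — a placeholder, not a measured value for
  1M5NI;
* **energy sharing in ionization**: total loss ΔE drawn from a
  1/ΔE²-weighted (binary-encounter-like) spectrum on [IP, (E+IP)/2]; the
  secondary receives ΔE − IP, the binding energy IP is deposited
  locally;
* **vibrational loss** a fixed 0.15 eV quantum; **electronic loss** the
  4.0 eV channel threshold;
* electrons below the tracking cutoff (default 0.1 eV, the data floor)
  deposit their residual locally — the standard thermalization
  convention;
* if no elastic DCS table is supplied, angular sampling falls back to a
  screened-Coulomb toy shape normalized to the set's elastic ICS. The
  fallback is explicitly synthetic (it is *not* 1M5NI physics) and its
  use is stamped into the run metadata. For speed, transport samples
  angles from inverse-CDF tables cached on a 48-node log-energy grid
  (nearest-node lookup); `sample_deflection()` builds the exact CDF at
  any requested energy.

Every track is audited: primary energy = Σ deposits + Σ terminal
residuals across the cascade, checked to 10⁻⁶ relative (it holds to
machine precision by construction; the audit guards future changes).
Below 0.7 eV no inelastic channel is open, so an electron above the
cutoff can only scatter elastically forever; the per-electron event cap
(default 10⁴) truncates such walks and flags the track.

## Problem sizes and numerical tolerances

The shipped tests audit 25 cascades at E₀ = 500 eV with a 1 eV cutoff
(every track is checked individually, so the per-track invariant gains
nothing from more primaries), use 10⁵ draws for all sampler-frequency
checks (3σ binomial or χ² at p > 0.01), 10⁵ draws for free-path means,
and a 90-point log grid for resonance-extraction recovery. Quadrature
oracles run at 10⁻¹⁰–10⁻¹¹ relative tolerance; DDCS normalization closes
to 10⁻⁶ relative on its own quadrature grid (721 μ-nodes). The
acceptance script draws 10⁵ fragments per statistic.

## What the synthetic generators do and do not emulate

`make_resonance_curve()` (smooth `a + b/E` plus Lorentzians),
`make_toy_dcs()` (screened-Coulomb angular shape) and
`make_angular_data()` (model intensities with multiplicative Gaussian
noise) produce inputs with retained ground truth. They emulate the
*structure* of the real inputs — smooth decaying backgrounds with
isolated resonances, forward-peaked elastic scattering, noisy angular
distributions — but none of their parameters are fitted to 1M5NI data.
Passing tests therefore demonstrate that the algorithms are correct on
inputs of the right shape, not that the extracted physical quantities for
1M5NI carry those accuracies: the real low-energy curve has overlapping
resonances and calculation artifacts, the real elastic DCS has
diffraction minima the toy shape lacks, and real angular data carry
correlated systematics beyond independent Gaussian noise.

## Known limitations

* The recommended tables inherit the uncertainties of their sources
  (≈ 10% for elastic/ionization/electronic, 20–25% for vibrational and
  attachment); the 70 eV row is internally inconsistent and flagged.
* Anion branching outside 3.1–4.7 eV, minor-channel shares, fragment KE
  scales, and all ionization bookkeeping parameters are package
  assumptions (flagged above and in the docs).
* Cation intensities are energy-independent by assumption.
* The rotational channel is qualitative by design.
* Transport is a single-component low-pressure vapor model: no
  condensed-phase effects, no water mixture, no fields.
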