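---
title: "A reduced femtosecond model of selectivity-filter dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced femtosecond model of selectivity-filter dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcsafilter)
```

## The model

`kcsafilter` implements a deliberately reduced, femtosecond-resolution
molecular-dynamics model of the selectivity filter (SF) of the KcsA
potassium channel — the narrow TVGYG-lined pore segment through which
dehydrated K⁺ ions and water molecules move in single file. The model keeps
exactly the degrees of freedom that the filter's conduction physics is
thought to hinge on and drops everything else:

* **Scaffold.** Six rings of four backbone carbonyl groups (one per
  tetramer strand) form an idealized four-fold-symmetric lattice. Carbons
  are pinned at a ring radius of 440 pm, rings 300 pm apart, so the lattice
  spans ~1.5 nm at standard length. Cage centers between adjacent oxygen
  rings define the binding sites S0 (extracellular) through S4, with S_cav
  one spacing below S4. Axial rescaling of the carbon lattice about its
  midpoint — radial coordinates untouched — is the single deformation
  studied.
* **Carbonyl rotors.** Each oxygen keeps a rigid 123 pm bond to its carbon
  and swings as a two-degree-of-freedom rotor about a rest orientation that
  points at the pore axis. The angular restoring torque is harmonic,
  $\kappa = m_O r_{CO}^2 (2\pi c \tilde k)^2$ with a default wavenumber of
  $\tilde k = 500\,\mathrm{cm^{-1}}$ (period 66.7 fs, $\kappa \approx
  22.3\,\mathrm{eV/rad^2}$). `bending_constants()` tabulates the
  wavenumber ↔ period ↔ stiffness conversions.
* **Charges.** The carbonyl carbon carries $+q$ and the oxygen system $-q$
  (default $q = 0.51\,e$, a typical backbone carbonyl polarity), with the
  negative charge split evenly between the oxygen center and a *lone-pair
  point* 82 pm beyond the oxygen on the C→O line, which rides rigidly with
  the rotor. K⁺ carries $+1\,e$; water is a rigid three-site molecule
  ($q_O = -0.82\,e$, $q_H = +0.41\,e$) with its center of mass on the axis.
  All pairs interact by bare Coulomb forces — the system is small enough
  that no cutoff is used.
* **Short-range walls.** A Born–Mayer wall $B\,e^{(r_0 - r)/\rho}$
  (shifted so energy and force vanish at an 800 pm cutoff) acts between
  closed-shell site pairs, with contact distances $r_0$ from ionic/van der
  Waals radii. The wall on the *lone-pair point* against K⁺ and water
  oxygen (contact 205 pm) is what an approaching ion actually runs into;
  it turns the oxygen-ring planes into inter-site barriers while the
  eight-fold coordinated cage centers stay attractive.
* **Motion.** Mobiles move only along the pore axis and cannot pass each
  other (single file, maintained dynamically by the walls and verified at
  every step). Waters additionally tumble as rigid rotors: the orientation
  is a full orthonormal frame advanced by exact rotation about the angular
  velocity vector, with an isotropic moment of inertia. A frame-based
  rotor was chosen over polar/azimuth angle coordinates because the
  typical water orientation — dipole along the pore axis — sits exactly at
  the coordinate singularity of the angle parametrization, and because
  frame rotation makes the site-force torque an exact generalized force,
  which the energy-conservation checks require.
* **Bath and boundaries.** The filter sits in the thermal bath of the
  surrounding protein: an Andersen-style thermostat resamples carbonyl
  angular velocities from the 310 K Maxwell–Boltzmann distribution at a
  default rate of 1/ps per oxygen. Mobiles are *not* thermostatted; they
  heat and cool only through their interactions with the vibrating
  oxygens. Injection attempts at S_cav arrive as a Poisson process
  (default 5/ps, a proxy for equal K⁺ and H₂O partial pressures in the
  cavity); an attempt succeeds only if the site is sterically free, and the
  species is drawn 50/50. Particles crossing the exit plane (150 pm above
  the top ring) or the cavity floor (450 pm below the bottom ring) are
  removed and logged as `emission_top` / `return_to_cavity`. A small
  axial driving field (default 100 mV across the domain) biases outward
  motion without suppressing back-hops. Setting `boundaries = FALSE`
  instead reflects particles at those planes — a closed box that holds a
  chosen occupancy fixed.

Integration is velocity Verlet at $\Delta t = 0.25$ fs, with the rigid-rotor
analog (half-kick on angular velocity, exact Rodrigues rotation of the
orientation, renormalization) for the angular degrees of freedom. All
randomness — thermal initialization, the bath, injection — derives from one
seed; identical configs give bit-identical event logs.

## Units

Internally everything is pm / fs / u / e, making the energy unit
u·pm²/fs² (1 eV = 96.485 of these). User-facing functions report pm, fs/ns,
eV, and ions/µs.

## Calibration of the free constants

The exact force expressions and charge magnitudes behind this class of
reduced filter models are not fixed by first principles; the physically
meaningful anchor is the height of the instantaneous energy barrier a
transiting ion faces between S1 and S0, which independent simulation work
places in the 0.5–0.8 eV (19–29 k_BT) band. The package therefore treats
the ring radius, the lone-pair charge split, and the Born–Mayer strength
and contacts as calibration knobs and froze them, once, so that
test-charge barrier snapshots of a thermalized `K0W1K2W3K4` + cavity-water
configuration at standard length fall in that band (the acceptance suite
re-measures this). The frozen values are the package defaults quoted
above; every one of them remains config-exposed.

A note on the barrier convention: with three K⁺ in the file, the bare
Coulomb tail of the ion at S2 tilts the whole S1→S0 interval by well over
1 eV, so *no* choice of filter constants can make a barrier appear in a
profile that includes the other mobiles as sources. Barrier snapshots are
therefore computed against the instantaneous *filter* charges (carbonyls
plus lone pairs; `exclude = "mobiles"` in `potential_profile()`), i.e. the
landscape that the vibrating oxygens modulate. The default
`exclude = "interval"` mode, which removes only the probed interval's
residents, remains available for transit-landscape analyses.

## The experiments

* **Conduction–length scan** (`length_scan()`, `fit_gaussian_current()`):
  independent seeded replicates at each axial length fraction, K⁺ current =
  production emissions / duration, per-length means ± SD, and a weighted
  nonlinear least-squares fit of
  $I(x) = I_0 e^{-(x - x_0)^2 / 2w^2}$ to the means.
* **Coordination mobility** (`oxygen_fluctuation_stats()`): deviations of
  the Tyr78-ring carbonyl oxygens (second ring from the extracellular top,
  the lower boundary of S0) from their per-oxygen trajectory means, pooled
  over the four ring oxygens; reports the mean Euclidean (3D) deviation —
  that is how "deviation along all spatial orientations" is interpreted
  here, stated in the output — the per-axis spreads, histograms, and the
  fraction of samples beyond a 12 pm threshold.
* **Barrier snapshots** (`potential_profile()`): a unit test charge scanned
  on the axis between two sites; barrier = profile maximum minus the
  preceding minimum on the inner side (both interval minima are reported).
* **Event statistics** (`event_statistics()`): per-ion residence times by
  id-matched injection/emission, inter-emission intervals, and bursts
  (emission clusters separated by less than a configurable 10 ps gap; the
  gap is a parameter precisely because burst counts are sensitive to it).

### Protocol choice for the mobility window

The mobility experiment compares a *fixed* high-occupancy configuration
(`K0W1K2W3K4` plus a cavity water) across filter lengths. The package runs
this window as a closed box (reflective boundaries, injection off) after a
20 ps thermalization — the model reaches thermal equilibrium from a cold
start within tens of picoseconds — recording every 0.25 fs step for 600 ps.
Holding the particle set fixed is what makes the three lengths comparable:
in this model's conduction regime the occupancy would otherwise turn over
within the window, and the statistic would measure transit noise rather
than coordination mobility.

## What the model does and does not show

The idealized lattice reproduces the site structure, spacing, and symmetry
of the real filter, but not its atomistic detail: there is no backbone
connectivity between carbonyls, no Thr75 hydroxyl, no protein/membrane
environment beyond the implicit bath, and no ion species other than K⁺.
Passing tests therefore certify the *mechanisms* of the reduced model —
harmonic coordination dynamics, Rayleigh-distributed oxygen excursions,
barrier modulation by lone-pair motion, single-file stop-and-go transport —
not quantitative fidelity to any particular channel structure.

One known divergence deserves emphasis: with bare Coulomb interactions
between file ions and the calibrated sub-eV filter barriers, injection
pressure drives conduction far faster than the experimental
several-10⁸ ions/s diffusion limit that motivated the model class. The
conduction-rate *machinery* (event logs, currents, residence, bursts) is
exercised on the model's own output, and the length response is probed by
the acceptance suite: the lengthened filter reliably jams and stops, as the
real channel's conduction curve suggests, but the shortened filter keeps
conducting in this regime, standard-length replicates straddle the
jam/flush transition with large variance, and the absolute current scale
should not be compared to experiment.

## Numerical choices

* Orientation constraint |u| = 1 by exact Rodrigues rotation plus
  renormalization each step; at 0.25 fs (267 steps per carbonyl period)
  the closed oscillator drifts less than 10⁻⁴ relative over 10⁵ steps.
* Shifted-force repulsion: value and slope both zero at the cutoff, so the
  energy is once-differentiable everywhere.
* Degenerate inputs fail loudly: coincident charges raise a
  singular-configuration error with the time stamp; profile grid points
  within 1 pm of a source are masked (`NA`) and counted; the Gaussian fit
  refuses all-zero curves and fewer than four lengths, and reports its
  starting values when the optimizer fails.
* Replicate seeds in `length_scan()` are derived deterministically from the
  base seed (31-bit linear map), so a scan is reproducible as a whole and
  any single replicate can be re-run in isolation.
* Problem sizes in the test and acceptance suites are desk-scale by
  design: 600 ps mobility windows (2.4 × 10⁶ steps, the size at which the
  tail statistic's Monte-Carlo error drops below the effects of interest),
  0.2 ns conduction replicates, 10⁵-step conservation runs. The full
  10 µs × 8-replicate protocol behind the conduction curve is exposed
  through the same functions (`length_scan(cfg, replicates = 8)` with
  `duration_ns = 10000`) for machines with the budget for it.

## Limitations

Beyond the conduction-scale divergence above: the isotropic-inertia water
rotor is a simplification (the true inertia tensor is anisotropic by a
factor ~3); lone-pair points carry no mass; the Andersen bath acts on
carbonyls only, so mobile temperatures are emergent rather than imposed;
and the driving field is a crude stand-in for the electrochemical gradient.
All are deliberate: the package's aim is a transparent, fully seeded,
testable realization of the reduced filter-dynamics model, not an all-atom
simulation.
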