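---
title: "The coarse-grained axon membrane-skeleton model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coarse-grained axon membrane-skeleton model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(axskel)
```

# The model

Super-resolution microscopy shows that the unmyelinated axon's membrane
skeleton is a periodic lattice: circumferential actin rings spaced about
185 nm apart along the axon, connected longitudinally by spectrin
tetramers whose midpoints are anchored to the lipid bilayer through
ankyrin, which in turn binds voltage-gated sodium (Nav) channels.
`axskel` implements a coarse-grained bead-spring molecular-dynamics model
of this lattice and the analyses used to interrogate its mechanics.

Three particle kinds:

* **Actin** (radius 17.5 nm): 39 beads per ring, joined cyclically by
  harmonic springs (`kA = 38.0 eps/sigma^2`, rest length 35 nm) plus a
  FENE bending restraint on every consecutive bead triple about the
  regular-polygon angle `theta0 = 180 * 37/39 = 170.77` degrees
  (`kb = 3500 kBT`, maximum deviation `0.3 theta0`). The 39 chords of
  35 nm close a ring of diameter ~434 nm.
* **Spectrin** (radius 2.5 nm): each tetramer is 41 beads joined by 40
  harmonic springs (`k0 = 3.56 eps/sigma^2`, rest length 5 nm, contour
  200 nm). All particle pairs additionally repel through a shifted,
  purely repulsive Lennard-Jones potential cut at its minimum; for
  spectrin-spectrin pairs the well depth is `eps/16`, chosen so the
  curvature at contact equals `k0`.
* **Ankyrin/Nav** (effective radius 12.5 nm): one bead per tetramer,
  tied to the tetramer's 20th bead by a `k0` spring of rest length 15 nm.

Spectrin ends associate with actin junction beads through a *breakable*
full Lennard-Jones attraction of depth `eps` and equilibrium distance
`2^(1/6) * 4 sigma ~ 20 nm`. The association breaks (its attraction is
switched off) when the pair distance crosses the inflexion point
`(26/7)^(1/6) * 4 sigma ~ 22.2 nm`, and a broken pair reforms when it
re-enters the capture distance `2.5 * 4 sigma ~ 44.5 nm`. The deep well
(`eps ~ 33 kBT`) reflects the observation that a weaker, red-blood-cell
scale association energy cannot hold a network whose spectrin is
stretched to a ~145 nm end-to-end distance.

The bilayer is not represented by particles. Its mechanical effect is a
radial harmonic confinement (`kc = 0.1 k0`): two-sided about 232 nm for
ankyrin (which is bound to the bilayer), one-sided (outward only) about
217 nm for spectrin (which may move inward freely but cannot cross the
bilayer). Microtubule/neurofilament scaffolding enters only as a FENE
restraint (`kmt = 477 kBT/sigma = 0.3 E_L pi R^2` with `E_L = 10 kPa`)
on the mean-z distance between consecutive ring centres.

Reduced units: `sigma = 4.45 nm` (fixed by the 5 nm spectrin contact),
`eps = kB * 300 K / 0.03 ~ 0.86 eV` (fixed by running at reduced
temperature `kT/eps = 0.03`), bead mass `m = 1`, time unit
`t_s = sqrt(m sigma^2/eps)`, step `dt = 0.01 t_s`. The bead mass is
never assigned an SI value; all reported observables are equilibrium
statistics, which are mass independent.

# Dynamics and sampling

Integration is the Beeman algorithm (bootstrapped by one velocity-Verlet
step), with a Berendsen weak-coupling thermostat (`tauT = 100 dt`, a
choice the model leaves open; weak coupling distorts fluctuation
statistics least). Initial velocities are Maxwell-Boltzmann at the
target temperature with the net linear momentum removed. Runs are
bit-reproducible functions of (configuration, seed).

Two sampling issues deserve attention, because they materially change
results and are invisible in a naive implementation:

* **Rigid-mode pumping.** Berendsen rescaling feeds energy into
  conserved, dissipation-free modes — net translation and net rotation of
  an isolated chain, or net azimuthal rotation of the axially symmetric
  axon — at the expense of internal modes (the "flying ice cube"
  artifact). Left alone, a free spectrin chain spins up and extends
  centrifugally toward its full contour length. For deterministic
  thermostatted runs the engine therefore removes the rigid modes
  periodically.
* **Slow conformational mixing.** An isolated bead-spring chain is
  nearly integrable: its conformational (bending) modes have no
  restoring force and exchange energy with bond vibrations very slowly,
  so purely deterministic trajectories sample the canonical ensemble
  poorly on any affordable run length. For free-chain statistics the
  engine therefore offers Andersen-style massive collisions (all
  velocities redrawn from Maxwell-Boltzmann every `andersen_stride`
  steps), run as the sole thermostat with Hamiltonian dynamics between
  collisions; they are canonical by construction, whereas layering
  Berendsen rescaling between collisions was found to overheat the
  softest modes. Constraining the angular
  momentum to zero *throughout* such a run would bias the configurational
  measure by `det(I)^(-1/2)` toward compact states, so drift removal is
  disabled when collisions are active. With collisions the chain
  statistics agree with an independent Metropolis Monte Carlo oracle
  (pivot + displacement moves) to within sampling error, and with the
  exact ideal-chain result when the sterics are switched off.

Equilibration of a freshly built axon runs in two phases (default
1.5e5 steps total, the published schedule): first with junction
break/recapture locked and per-particle force capping while the
idealized built geometry relaxes, then with the full dynamics. Spectrin
chains are built as zigzags at the full bond rest length between their
junctions so they do not start inside the steric repulsion.

# The in-silico experiments

## Free-chain statistics

`free_filament_stats()` measures the thermal end-to-end distance of the
free 41-bead tetramer and infers a persistence length via
`<ree^2> = 2 lp Lc`. With the published Hamiltonian and temperature our
canonically sampled chain gives an RMS end-to-end distance of ~53 nm
(`lp ~ 7 nm`), cross-checked against the Monte Carlo oracle (53.2 nm).
The published value is 74.3 nm (`lp = 13.8 nm`). We could not find any
reading of the stated chain Hamiltonian that reproduces 74.3 nm at
equilibrium — excluded-volume variants span 54-62 nm — while a
Berendsen-thermostatted run *without* rigid-mode handling drifts to
~180-195 nm. We therefore report the equilibrium value our
implementation actually produces rather than tune toward the printed
one; the discrepancy and its likely origin (rigid-mode pumping and/or
incomplete relaxation from a straight initial state in the original
runs) are documented here deliberately.

## Radial-expansion stiffness

`radial_expansion()` inflates the skeleton with an internal repulsive
cylindrical wall (length scale ~sigma against spectrin, ~7 sigma against
actin, zero force once a particle centre is beyond `r_c + r_kind`),
growing `r_c` from 217 nm to 227 nm in twenty 0.5 nm increments (1000
transition steps, 1000 relaxation steps, and a measurement window — 8000
steps by default — per increment). The outward wall force is accumulated
per step over 80 nm stripes centred on the rings, the complementary
105 nm stripes, and their union; stripe pressure is total force divided
by the lateral stripe area `2 pi r_c w`. The slope of mean pressure
versus expansion is fitted by ordinary least squares and inverted with
thin-shell theory `E = p R^2/(delta H)` (`R = 217 nm`, `H = 10 nm`).

Two protocol details are the package's own choices, because the
experiment cannot run as literally stated:

* At `r_c = 217 nm` the wall-actin interaction (contact at
  `r_c + r_A = 234.5 nm`) already overlaps rings of radius ~217 nm
  deeply; switching it on instantly would inject enormous energy. The
  wall is therefore ramped in from well inside the skeleton over 3e4
  steps before the measured expansion starts.
* While the wall is active the confinement radii track it
  (`conf_track = TRUE`): the confinement stands in for the bilayer, and
  an inflation that moves the skeleton but pins the bilayer would simply
  measure the confinement springs (tens of MPa, two orders above
  everything else in the model) rather than the skeleton.

With these choices the measured moduli are dominated by ring hoop
elasticity at the rings (scaling with `kA`) and are near zero between
the rings (nothing connects the network circumferentially there), with
the whole-axon value the stripe-area-weighted mean of the two — the same
qualitative structure as published. The absolute scale, however, comes
out in the MPa range, about 10^3 times the published kPa values; a
ring of `kA = 0.26 N/m` springs stretched 10 nm stores far more elastic
energy than kPa-scale pressures can account for, so we believe the
published pressure normalization differs from its stated definition
(total stripe force over stripe area) by a constant factor of that
order. The package reports the honestly computed values.

## Ankyrin thermal motion

`ankyrin_motion()` records ankyrin positions at a fixed stride and
reports (i) the mean planar trajectory radius — per ankyrin, the RMS
deviation from its own mean position in the local membrane plane
(axial z and circumferential arc), averaged over ankyrins — and (ii) the
standard deviation `s` of the pooled normalized longitudinal deviations
`d(z)/Lc`, with `Lc` the measured mean z-spacing between consecutive
ankyrin rows. "Trajectory radius" is operationalized as the RMS planar
deviation; an enclosing-circle radius would be larger and
sample-size-dependent. The under-tension (185 nm) and near-equilibrium
(110 nm) configurations are compared; the published panel labelling of
the two `s` values is internally ambiguous, so the package simply
reports both configurations and the acceptance analysis uses the larger.

## Laceration

`lacerate_and_watch()` severs 15 angularly contiguous tetramers in one
gap at their junction with the first bounding ring (severing one end per
filament; the published description does not say one or both), relaxes
with recapture suppressed for the severed pairs, then re-enables
recapture and counts severed pairs that return to their *original*
junction. Severed chains contract toward their thermal end-to-end
length, so reconnection is geometrically impossible at 185 nm spacing
and easy at 110 nm — the behaviour the experiment is designed to show.

## AFM force curves

Independently of the bead-spring model, `predict_force()`,
`fit_modulus()` and `summarize_grid()` implement the closed-form
force-indentation power laws for a thin-walled cylinder
(`F = 4.41e-3 E d^1.37`) and a rectangular cuboid
(`F = 7.95e-3 E d^1.46`), with `d` in nm, `E` in kPa, `F` in pN; the
modulus is the single linear free parameter per curve, fitted by least
squares on the first ~100 nm of indentation, and grids of fits are
reduced to a median with a robust spread. The finite-element derivation
behind the exponents is out of scope; the printed fits are taken as
given.

# Problem sizes and what the tests show

Desk-scale runs use 2-3 rings (1716-3393 particles) and 1e5-2e6 steps;
stiffness and per-filament statistics are intensive, so they do not
require the published full-size system (11 rings, ~1.85 um, 1e7-step
production). The test suite validates mechanics against independent
oracles (closed-form oscillators, finite-difference gradients, Monte
Carlo chain statistics, Taylor expansions of the FENE forms) rather than
against the published headline numbers; the acceptance analysis
(`scripts/acceptance.R`) recomputes the headline numbers and reports
them as measured.

Known limitations: no explicit bilayer, solvent or hydrodynamics, so
time scales are not physical and only equilibrium statistics should be
interpreted; no actin (re)polymerization; the synthetic AFM noise model
is multiplicative Gaussian only (no adhesion or drift); and the three
published quantitative disagreements discussed above (free-chain
end-to-end distance, stiffness scale, and the ankyrin trajectory radius,
where we measure ~19 nm against a published 5.37 nm — a taut-string
estimate `kT L/(4T)` already exceeds 8 nm for any tension consistent
with the chain model) are reported as computed, not reconciled.
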