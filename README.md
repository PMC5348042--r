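# axskel

Coarse-grained molecular dynamics of the axon membrane skeleton, in R.

The unmyelinated axon's plasma-membrane skeleton is a periodic lattice:
circumferential **actin rings** (~434 nm diameter) spaced ~185 nm along
the axon, connected longitudinally by **spectrin tetramers** (~200 nm
contour, held under entropic tension), each anchored at its midpoint to
the lipid bilayer through an **ankyrin** particle that carries a
voltage-gated sodium (Nav) channel. `axskel` builds this lattice as a
bead-spring model and runs the in-silico experiments that probe its
mechanics, for researchers studying axon mechanics, Nav channel
organization, or cytoskeletal network elasticity.

The force field combines:

* harmonic bonds — spectrin–spectrin (`k0 = 3.56 eps/sigma^2`, rest 5 nm),
  actin–actin (`kA = 38 eps/sigma^2 ~ 0.26 N/m`, rest 35 nm),
  ankyrin–spectrin (`k0`, rest 15 nm);
* FENE restraints — ring bending about `theta0 = 170.77 deg`
  (`kb = 3500 kBT`) and inter-ring spacing about 185 nm
  (`kmt = 477 kBT/sigma = 0.3 E_L pi R^2`, the implicit
  microtubule/neurofilament scaffold);
* shifted, purely repulsive Lennard-Jones sterics between all particle
  pairs, cut at contact;
* a **breakable** actin–spectrin junction: full Lennard-Jones attraction
  (depth `eps = kB T/0.03 ~ 0.86 eV`, equilibrium ~20 nm) that breaks past
  its inflexion point (~22.2 nm) and re-forms inside a 44.5 nm capture
  radius;
* one-sided (spectrin) and two-sided (ankyrin) radial harmonic
  confinement standing in for the bilayer, and an expanding cylindrical
  wall used to apply internal radial pressure.

Dynamics are NVT: Beeman integration (`dt = 0.01 t_s`) with a Berendsen
thermostat at reduced temperature `kB T / eps = 0.03`, with optional
Andersen-style velocity resampling for ergodic free-chain sampling.
Everything is deterministic given a configuration and a seed.

Reduced units: `sigma = 4.45 nm`, `eps = 0.86 eV`
(`eps/sigma^3 = 1.567 MPa`, `eps/sigma^2 = 6.97 mN/m`); see
`axon_units()` / `to_SI()`.

## A worked example

```r
library(axskel)

# build the default three-ring axon (117 actin + 3198 spectrin + 78
# ankyrin = 3393 particles) and equilibrate it
ax <- make_preset("axon_3ring", seed = 1)
eq <- equilibrate(ax, n_steps = 1.5e5)

# Nav channel density implied by the geometry: one channel per ankyrin
channel_density(ax)
#> [1] 154.3  # channels per um^2, inside the physiological 110-300 range

# thermal statistics of a free spectrin tetramer
fs <- free_filament_stats(model_config(seed = 1), production_steps = 1e6)
round(c(rms = fs$rms_ree_nm, lp = fs$lp_nm), 1)
#>  rms   lp
#> 53.4  7.1   # nm: RMS end-to-end distance and persistence length

# AFM force-indentation analysis (thin-walled cylinder geometry):
predict_force(4.6, 100, "thin_cylinder")   # 4.6 kPa at 100 nm depth
#> [1] 11.15  # pN
grid <- make_afm_dataset(E_true = 4.6, n_curves = 256, noise_frac = 0.1,
                         seed = 1)
fits <- vapply(grid$curves,
               function(cu) fit_modulus(cu, "thin_cylinder")$E_kPa,
               numeric(1))
summarize_grid(fits)$median_kPa
#> [1] 4.6   # the 16 x 16 grid recovers the ground-truth modulus
```

The free-chain numbers deserve a note: the model's spectrin tetramer
coils to an RMS end-to-end distance of ~53 nm (persistence length
~7 nm) at equilibrium, verified against an independent Monte Carlo
oracle of the identical Hamiltonian. In the assembled axon the tetramers
are held at ~145 nm, i.e. strongly stretched, which is what confines the
thermal motion of the attached ankyrin/Nav particles and what prevents
severed tetramers from re-finding their junctions at the native ring
spacing (`lacerate_and_watch()`), while at slack ring spacings severed
tetramers reconnect readily. The radial-expansion experiment
(`radial_expansion()`) measures stripe pressures under an inflating
cylindrical wall and inverts them with thin-shell theory into Young's
moduli at the rings, between the rings, and overall. The methods
vignette (`vignettes/axon-skeleton-model.Rmd`) documents the model,
the sampling pitfalls the implementation corrects for, and the places
where the honestly computed observables disagree with previously
reported values.

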