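#' Harmonic bond potential
#'
#' `U(r) = 1/2 k (r - r_eq)^2`, used for spectrin-spectrin bonds (`k0`),
#' actin-actin ring bonds (`kA`) and the ankyrin-spectrin anchor (`k_SK`).
#'
#' @param r Bond length(s), reduced units; must be positive.
#' @param k Spring constant, eps/sigma^2.
#' @param r_eq Rest length, sigma.
#' @return List with `energy` and `force` (radial force `-k (r - r_eq)`;
#'   negative = pulling the beads together).
#' @export
harmonic_bond <- function(r, k, r_eq) {
  stopifnot(all(r > 0))
  list(energy = 0.5 * k * (r - r_eq)^2, force = -k * (r - r_eq))
}

#' Shifted, purely repulsive Lennard-Jones potential
#'
#' `U(r) = 4 eps_pair [(s/r)^12 - (s/r)^6] + eps_pair` for
#' distances below the cutoff `2^(1/6) s`, zero beyond. The shift makes
#' the energy continuous and
#' non-negative; the cutoff at the minimum makes the force purely
#' repulsive. Used for the steric interactions between all particle pairs.
#'
#' @param r Distance(s), reduced units.
#' @param eps_pair Well depth.
#' @param sigma_pair Length scale `s`.
#' @return List with `energy`, `force` (outward, >= 0) and `capped`
#'   (TRUE where `r` is so small that the force exceeds the engine's cap,
#'   signalling step rejection).
#' @export
repulsive_lj <- function(r, eps_pair, sigma_pair) {
  stopifnot(all(r > 0))
  cut <- 2^(1 / 6) * sigma_pair
  s6 <- (sigma_pair / r)^6
  inside <- r < cut
  e <- ifelse(inside, 4 * eps_pair * (s6^2 - s6) + eps_pair, 0)
  f <- ifelse(inside, 24 * eps_pair * (2 * s6^2 - s6) / r, 0)
  list(energy = e, force = f, capped = f > 1e3)
}

#' FENE bending potential for actin rings
#'
#' `U(theta) = -1/2 kb dtheta_max log[1 - ((theta - theta0)/dtheta_max)^2]`,
#' harmonic with stiffness `kb/dtheta_max` for small deviations and
#' diverging as `|theta - theta0| -> dtheta_max`.
#'
#' @param theta Angle(s), radians.
#' @param kb Bending stiffness parameter, eps (the model uses 3500 kB*T).
#' @param theta0 Equilibrium angle, radians.
#' @param dtheta_max Maximum deviation, radians.
#' @return List with `energy` and `torque` (`-dU/dtheta`).
#' @export
fene_angle <- function(theta, kb, theta0, dtheta_max) {
  t <- (theta - theta0) / dtheta_max
  if (any(abs(t) >= 1))
    stop("FENE bending restraint exceeded: |theta - theta0| >= dtheta_max")
  list(energy = -0.5 * kb * dtheta_max * log(1 - t^2),
       torque = -kb * t / (1 - t^2))
}

#' Breakable actin-spectrin association
#'
#' Full Lennard-Jones attraction `4 eps [(s/r)^12 - (s/r)^6]` with
#' `s = junction_eq / 2^(1/6)` (~4 sigma) while intact. The association
#' breaks (attraction switched off) when `r` exceeds the inflexion point
#' `(26/7)^(1/6) s`, and reforms when a broken pair comes within the
#' capture distance `2.5 s`. A broken pair retains the purely repulsive
#' core below the equilibrium distance.
#'
#' @param r Distance, reduced units (scalar).
#' @param state `"intact"` or `"broken"`.
#' @param params Reduced parameter list from [reduced_params()] (uses
#'   `as_sigma`, `as_r_inflex`, `as_r_capture`).
#' @return List with `energy`, `force` (`-dU/dr`; negative = attractive)
#'   and `new_state` after applying the break/recapture rules at `r`.
#' @export
as_attraction <- function(r, state = c("intact", "broken"),
                          params = reduced_params(model_config())) {
  state <- match.arg(state)
  stopifnot(length(r) == 1, r > 0)
  s <- params$as_sigma
  new_state <- state
  if (state == "intact" && r > params$as_r_inflex) new_state <- "broken"
  if (state == "broken" && r < params$as_r_capture) new_state <- "intact"
  if (new_state == "intact") {
    s6 <- (s / r)^6
    e <- 4 * (s6^2 - s6)
    f <- 24 * (2 * s6^2 - s6) / r
  } else {
    rl <- repulsive_lj(r, 1, s)
    e <- rl$energy
    f <- rl$force
  }
  list(energy = e, force = f, new_state = new_state)
}

#' Inter-ring FENE coupling
#'
#' FENE restraint on the z-distance between the centres (mean z of the 39
#' beads) of consecutive actin rings, standing in for the
#' microtubule/neurofilament scaffolding that maintains the 185 nm ring
#' period. The axial force is distributed equally over the beads of each
#' ring (chain rule through the mean).
#'
#' @param ring_centers Numeric vector of ring-centre z coordinates
#'   (reduced units, ordered along the axon).
#' @param kmt FENE stiffness, eps/sigma.
#' @param deq Equilibrium ring spacing, sigma.
#' @param ddmax Maximum deformation, sigma.
#' @param n_beads Beads per ring over which each ring's force is spread.
#' @return List with `energy` and `force_per_bead`, a matrix with one row
#'   per ring giving the axial force on each of its beads.
#' @export
ring_coupling <- function(ring_centers, kmt, deq, ddmax, n_beads = 39) {
  ng <- length(ring_centers)
  stopifnot(ng >= 2)
  fz <- numeric(ng)
  e <- 0
  for (g in seq_len(ng - 1)) {
    d <- ring_centers[g + 1] - ring_centers[g]
    u <- (d - deq) / ddmax
    if (abs(u) >= 1)
      stop("inter-ring FENE restraint exceeded: |d - deq| >= ddmax")
    e <- e - 0.5 * kmt * ddmax * log(1 - u^2)
    dEdd <- kmt * u / (1 - u^2)
    fz[g] <- fz[g] + dEdd
    fz[g + 1] <- fz[g + 1] - dEdd
  }
  list(energy = e, force_per_bead = cbind(ring = seq_len(ng),
                                          fz = fz / n_beads))
}

#' Bilayer confinement potential
#'
#' Harmonic restraint on the radial (distance-from-axis) coordinate that
#' stands in for the lipid bilayer: two-sided about `r0_ankyrin` for
#' ankyrin (attached to the bilayer), one-sided (outward only) about
#' `r0_spectrin` for spectrin, which may move inward freely but cannot
#' cross the bilayer. Actin is unconfined.
#'
#' @param r_radial Radial distance(s) from the axon axis, sigma.
#' @param kind Particle kind: `"spectrin"` or `"ankyrin"`.
#' @param params Reduced parameter list (uses `kc`, `r0_spectrin`,
#'   `r0_ankyrin`).
#' @return List with `energy` and `force` (radial; negative = inward).
#' @export
confinement <- function(r_radial, kind = c("spectrin", "ankyrin"),
                        params = reduced_params(model_config())) {
  kind <- match.arg(kind)
  r0 <- if (kind == "spectrin") params$r0_spectrin else params$r0_ankyrin
  dev <- r_radial - r0
  if (kind == "spectrin") dev <- pmax(dev, 0)
  list(energy = 0.5 * params$kc * dev^2, force = -params$kc * dev)
}

#' Expanding cylindrical wall potential
#'
#' Purely repulsive Lennard-Jones interaction between a particle and an
#' expanding cylindrical surface of radius `r_c`, used to apply internal
#' radial pressure: `U = 4 eps [(s/d)^12 - (s/d)^6]` with
#' `d = r_i - (r_c - r_kind)` and length scale `s = 2 r_kind / 2^(1/6)`
#' (~sigma for spectrin, ~7 sigma for actin), cut at `d = 2 r_kind`, i.e.
#' zero force once the particle centre is beyond `r_c + r_kind`. Acts on
#' spectrin and actin only.
#'
#' @param r_radial Radial particle distance(s) from the axis, sigma.
#' @param kind `"spectrin"` or `"actin"`.
#' @param r_c Wall radius, sigma; `NULL` or negative = wall inactive.
#' @param params Reduced parameter list (uses `r_wall_S`, `r_wall_A`).
#' @return List with `energy` and `force` (radial, outward >= 0);
#'   `capped` flags particles at/inside the singularity radius.
#' @export
expansion_wall <- function(r_radial, kind = c("spectrin", "actin"),
                           r_c = NULL,
                           params = reduced_params(model_config())) {
  kind <- match.arg(kind)
  if (is.null(r_c) || r_c <= 0)
    return(list(energy = rep(0, length(r_radial)),
                force = rep(0, length(r_radial)),
                capped = rep(FALSE, length(r_radial))))
  rk <- if (kind == "spectrin") params$r_wall_S else params$r_wall_A
  s <- 2 * rk / 2^(1 / 6)
  d <- r_radial - (r_c - rk)
  capped <- d <= 0.05 * s
  d <- pmax(d, 0.05 * s)
  inside <- d < 2 * rk
  s6 <- (s / d)^6
  e <- ifelse(inside, 4 * (s6^2 - s6) + 1, 0)
  f <- ifelse(inside, 24 * (2 * s6^2 - s6) / d, 0)
  list(energy = e, force = f, capped = capped & inside)
}

#' Total forces and potential energy of a configuration
#'
#' Evaluates every active force-field term (bonds, ring bending,
#' inter-ring coupling, breakable junctions at their current state,
#' all-pairs sterics, confinement, optional expansion wall) via the
#' compiled engine.
#'
#' @param system An `axskel_system`.
#' @param topology Matching topology list.
#' @param wall_rc Wall radius in sigma (`NULL` = inactive).
#' @param conf_track If `TRUE`, confinement radii follow the wall radius.
#' @return List with `forces` (N x 3 matrix, reduced units), `energy`
#'   (total potential) and `breakdown` (per-term energies).
#' @export
total_forces <- function(system, topology, wall_rc = NULL,
                         conf_track = FALSE) {
  params <- reduced_params(system$config, topology)
  res <- cpp_energy_forces(system$pos, system$kind, topology, params,
                           if (is.null(wall_rc)) -1 else wall_rc,
                           as.integer(conf_track))
  res
}
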