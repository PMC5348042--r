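#' NVT dynamics: Beeman integrator with Berendsen thermostat
#'
#' Advances a built system by `n_steps` steps of `dt = 0.01 t_s` using the
#' Beeman algorithm (bootstrapped with one velocity-Verlet step) at
#' constant volume, with optional Berendsen velocity rescaling toward
#' `kB*T/eps = 0.03`. All randomness (initial Maxwell-Boltzmann
#' velocities, thermostat reseeding) derives from `seed`, so identical
#' inputs give bit-identical trajectories.
#'
#' Observers are sampled at fixed strides: particle trajectories
#' (`traj_stride`/`traj_idx`), thermodynamic log (`thermo_stride`), live
#' junction states (`as_log_stride`), and wall-pressure samples on the
#' steps flagged in `measure_steps`.
#'
#' @param system An `axskel_system` (positions in reduced units).
#' @param topology Matching topology list.
#' @param n_steps Number of time steps (0 = return the input state).
#' @param seed Integer seed; defaults to the configuration seed.
#' @param thermostat Apply Berendsen rescaling?
#' @param tauT Thermostat coupling time in units of t_s (default 100 dt:
#'   weak coupling that leaves fluctuation statistics intact).
#' @param reinit_vel Draw fresh Maxwell-Boltzmann velocities (with zero
#'   total momentum) before integrating?
#' @param cap_force Per-particle force cap in eps/sigma (0 = off). Used
#'   during equilibration to survive the artificial built state; must be
#'   0 during measurements.
#' @param as_dynamic Enable junction break/recapture transitions?
#' @param suppress_capture Logical vector (one per junction pair):
#'   recapture suppressed for flagged pairs.
#' @param traj_stride,traj_idx Record positions of particles `traj_idx`
#'   every `traj_stride` steps (0 = off).
#' @param thermo_stride Log step, instantaneous kT, potential and kinetic
#'   energy every this many steps (0 = off).
#' @param as_log_stride Record junction states every this many steps.
#' @param andersen_stride Every this many steps, redraw all velocities
#'   from the Maxwell-Boltzmann distribution (Andersen-style massive
#'   collision; 0 = off). Used for free-chain statistics, where purely
#'   deterministic dynamics mixes conformational modes too slowly to
#'   sample the canonical ensemble.
#' @param wall_rc Expansion-wall radius schedule: `NULL` (inactive), a
#'   scalar, or a vector of length `n_steps` (sigma).
#' @param conf_track Confinement radii follow the wall radius?
#' @param measure_steps Logical vector of length `n_steps`: record wall
#'   stripe forces on these steps.
#' @param deq_schedule Ring-spacing target schedule: `NULL`, scalar, or
#'   length-`n_steps` vector (sigma); implements the gradual approach to
#'   a new equilibrium length.
#' @param ring_half_width_nm Half-width of the ring stripes used for
#'   pressure accounting (40 nm: 80 nm bands centred on ring planes).
#' @return List with the updated `system`, `topology` (junction states
#'   updated), and data frames `thermo`, `traj`, `pressure`, `as_log`.
#' @export
run_nvt <- function(system, topology, n_steps,
                    seed = NULL,
                    thermostat = TRUE, tauT = NULL,
                    reinit_vel = TRUE, cap_force = 0,
                    as_dynamic = TRUE, suppress_capture = NULL,
                    traj_stride = 0L, traj_idx = integer(0),
                    thermo_stride = 0L, as_log_stride = 0L,
                    andersen_stride = 0L,
                    wall_rc = NULL, conf_track = FALSE,
                    measure_steps = NULL, deq_schedule = NULL,
                    ring_half_width_nm = 40) {
  stopifnot(inherits(system, "axskel_system"), n_steps >= 0)
  cfg <- system$config
  params <- reduced_params(cfg, topology)
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(tauT)) tauT <- 100 * cfg$dt
  if (n_steps == 0)
    return(list(system = system, topology = topology,
                thermo = NULL, traj = NULL, pressure = NULL,
                as_log = NULL))
  opts <- list(
    n_steps = as.integer(n_steps),
    thermostat = thermostat, tauT = tauT,
    cap_force = cap_force, reinit_vel = reinit_vel,
    seed = as.integer(seed) %% .Machine$integer.max,
    as_dynamic = as_dynamic,
    traj_stride = as.integer(traj_stride),
    traj_idx = as.integer(traj_idx),
    thermo_stride = as.integer(thermo_stride),
    as_log_stride = as.integer(as_log_stride),
    andersen_stride = as.integer(andersen_stride),
    wall_rc = if (is.null(wall_rc)) numeric(0) else as.numeric(wall_rc),
    conf_track = as.integer(conf_track),
    measure_steps = if (is.null(measure_steps)) logical(0)
                    else measure_steps,
    deq_schedule = if (is.null(deq_schedule)) numeric(0)
                   else as.numeric(deq_schedule),
    suppress_capture = if (is.null(suppress_capture)) logical(0)
                       else suppress_capture,
    ring_half_width = nm_to_red(ring_half_width_nm, cfg$us)
  )
  res <- cpp_run_md(system$pos, system$vel, system$kind, system$clamped,
                    topology, params, opts)
  system$pos <- res$pos
  system$vel <- res$vel
  topology$as_state <- res$as_state

  traj <- NULL
  if (traj_stride > 0 && length(traj_idx) > 0 && nrow(res$traj) > 0) {
    traj <- data.frame(step = res$traj[, 1],
                       particle = rep(as.integer(traj_idx),
                                      nrow(res$traj) / length(traj_idx)),
                       x = res$traj[, 2], y = res$traj[, 3],
                       z = res$traj[, 4])
  }
  thermo <- NULL
  if (thermo_stride > 0) {
    thermo <- as.data.frame(res$thermo)
    names(thermo) <- c("step", "kT_inst", "E_pot", "E_kin")
  }
  pressure <- NULL
  if (!is.null(measure_steps) && nrow(res$pressure) > 0) {
    pressure <- as.data.frame(res$pressure)
    names(pressure) <- c("step", "r_c", "F_ring", "F_between", "F_all")
  }
  as_log <- if (as_log_stride > 0) res$as_log else NULL

  list(system = system, topology = topology, thermo = thermo,
       traj = traj, pressure = pressure, as_log = as_log,
       fene_overrun = res$fene_overrun)
}

#' Equilibrate a freshly built system
#'
#' Standard preparation before measurements: Maxwell-Boltzmann velocities
#' at the target temperature, Berendsen thermostat on, and per-particle
#' force capping to absorb the idealized built geometry (straight,
#' compressed spectrin chains). The published schedule equilibrates for
#' 1.5e5 steps before production.
#'
#' @param build A list with `system` and `topology` (from a builder).
#' @param n_steps Equilibration steps.
#' @param seed RNG seed (default: configuration seed).
#' @param cap_force Force cap during equilibration, eps/sigma.
#' @param ... Passed to [run_nvt()].
#' @return Updated `list(system, topology)`.
#' @export
equilibrate <- function(build, n_steps = 150000, seed = NULL,
                        cap_force = 1000, ...) {
  # phase 1: junction dynamics locked while the built state relaxes, so
  # the initial conformational energy release cannot tear the network
  res <- run_nvt(build$system, build$topology, n_steps = ceiling(n_steps / 2),
                 seed = seed, thermostat = TRUE, reinit_vel = TRUE,
                 cap_force = cap_force, as_dynamic = FALSE, ...)
  # phase 2: full dynamics including junction break/recapture
  res <- run_nvt(res$system, res$topology, n_steps = floor(n_steps / 2),
                 seed = if (is.null(seed)) NULL else seed + 1L,
                 thermostat = TRUE, reinit_vel = FALSE,
                 cap_force = cap_force, as_dynamic = TRUE, ...)
  list(system = res$system, topology = res$topology)
}
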