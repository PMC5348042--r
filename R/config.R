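#' Model configuration for the axon membrane skeleton
#'
#' Collects the geometry and force-field parameters of the coarse-grained
#' axon skeleton model. Defaults are the published model values: rings of
#' 39 actin beads (35 nm diameter each, ring diameter ~434 nm) spaced
#' 185 nm apart along the axon, 39 spectrin tetramers per inter-ring gap,
#' each a chain of 41 beads (5 nm bond rest length, 200 nm contour), one
#' ankyrin/Nav bead per tetramer attached to the 20th spectrin bead.
#'
#' Mixed-unit parameters follow the model's conventions: spring constants
#' in `eps/sigma^2`, the ring bending stiffness `kb_kBT` in units of kB*T,
#' the inter-ring stiffness `kmt_kBT_sigma` in kB*T per sigma.
#'
#' @param n_rings Number of actin rings (>= 2 for an axon).
#' @param ring_spacing_nm Equilibrium distance between consecutive ring
#'   centres, nm (185 for the axon under tension; 110 puts the spectrin
#'   near its thermal equilibrium end-to-end distance).
#' @param particles_per_ring Beads per actin ring (39).
#' @param actin_bead_diameter_nm Actin bead diameter / AA bond rest length, nm.
#' @param filaments_per_gap Spectrin tetramers per inter-ring gap (39).
#' @param beads_per_filament Beads per spectrin tetramer (41).
#' @param spectrin_bond_eq_nm Spectrin-spectrin bond rest length, nm.
#' @param junction_eq_nm Actin-spectrin association equilibrium distance,
#'   nm; one of 20, 15, 10, 5 unless `junction_override = TRUE`.
#' @param junction_override Allow junction_eq_nm outside the standard set.
#' @param ankyrin_attach_index Spectrin bead (1-based) carrying the ankyrin
#'   anchor (20).
#' @param spectrin_confine_radius_nm Bilayer confinement radius for
#'   spectrin (one-sided, outward), nm.
#' @param ankyrin_confine_radius_nm Bilayer confinement radius for ankyrin
#'   (two-sided), nm.
#' @param k0 Spectrin bond spring constant, eps/sigma^2.
#' @param eps1_over_eps Steric repulsion well depth as a fraction of eps.
#' @param kA Actin-actin ring spring constant, eps/sigma^2.
#' @param kb_kBT FENE ring-bending stiffness, kB*T.
#' @param dtheta_max_frac Maximum FENE bending deviation as a fraction of
#'   the equilibrium angle theta0.
#' @param kmt_kBT_sigma Inter-ring FENE stiffness, kB*T/sigma.
#' @param dd_max_frac Maximum inter-ring FENE deviation as a fraction of
#'   the ring spacing.
#' @param kc_frac Confinement stiffness as a fraction of k0.
#' @param k_SK Ankyrin-spectrin spring constant, eps/sigma^2.
#' @param sk_eq_nm Ankyrin-spectrin bond rest length, nm.
#' @param dt Integration time step in units of t_s.
#' @param seed RNG seed used for initial velocities and thermal noise.
#' @param us Unit system from [axon_units()].
#' @return An object of class `axskel_config` (a validated list, with
#'   derived fields `theta0_deg` and `ring_radius_nm`).
#' @examples
#' cfg <- model_config(n_rings = 3)
#' cfg$theta0_deg      # 170.77
#' cfg$ring_radius_nm  # ~217
#' @export
model_config <- function(n_rings = 3,
                         ring_spacing_nm = 185,
                         particles_per_ring = 39,
                         actin_bead_diameter_nm = 35,
                         filaments_per_gap = 39,
                         beads_per_filament = 41,
                         spectrin_bond_eq_nm = 5,
                         junction_eq_nm = 20,
                         junction_override = FALSE,
                         ankyrin_attach_index = 20,
                         spectrin_confine_radius_nm = 217,
                         ankyrin_confine_radius_nm = 232,
                         k0 = 3.56,
                         eps1_over_eps = 1 / 16,
                         kA = 38.0,
                         kb_kBT = 3500,
                         dtheta_max_frac = 0.3,
                         kmt_kBT_sigma = 477,
                         dd_max_frac = 0.3,
                         kc_frac = 0.1,
                         k_SK = 3.56,
                         sk_eq_nm = 15,
                         dt = 0.01,
                         seed = 1L,
                         us = axon_units()) {
  counts <- c(n_rings = n_rings, particles_per_ring = particles_per_ring,
              filaments_per_gap = filaments_per_gap,
              beads_per_filament = beads_per_filament)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("particle counts must be positive integers")
  pos_pars <- c(ring_spacing_nm, actin_bead_diameter_nm, spectrin_bond_eq_nm,
                junction_eq_nm, spectrin_confine_radius_nm,
                ankyrin_confine_radius_nm, k0, kA, kb_kBT, kmt_kBT_sigma,
                k_SK, sk_eq_nm, dt, eps1_over_eps, dtheta_max_frac,
                dd_max_frac, kc_frac)
  if (any(!is.finite(pos_pars)) || any(pos_pars <= 0))
    stop("all model parameters must be positive and finite")
  if (!junction_override && !junction_eq_nm %in% c(5, 10, 15, 20))
    stop("junction_eq_nm must be one of 5, 10, 15, 20 ",
         "(set junction_override = TRUE to use another value)")
  if (ankyrin_attach_index < 1 || ankyrin_attach_index > beads_per_filament)
    stop("ankyrin_attach_index out of range")

  theta0_deg <- 180 * (particles_per_ring - 2) / particles_per_ring
  ring_radius_nm <- actin_bead_diameter_nm / (2 * sin(pi / particles_per_ring))

  cfg <- list(
    n_rings = as.integer(n_rings),
    ring_spacing_nm = ring_spacing_nm,
    particles_per_ring = as.integer(particles_per_ring),
    actin_bead_diameter_nm = actin_bead_diameter_nm,
    filaments_per_gap = as.integer(filaments_per_gap),
    beads_per_filament = as.integer(beads_per_filament),
    spectrin_bond_eq_nm = spectrin_bond_eq_nm,
    junction_eq_nm = junction_eq_nm,
    ankyrin_attach_index = as.integer(ankyrin_attach_index),
    spectrin_confine_radius_nm = spectrin_confine_radius_nm,
    ankyrin_confine_radius_nm = ankyrin_confine_radius_nm,
    k0 = k0, eps1_over_eps = eps1_over_eps, kA = kA,
    kb_kBT = kb_kBT, dtheta_max_frac = dtheta_max_frac,
    kmt_kBT_sigma = kmt_kBT_sigma, dd_max_frac = dd_max_frac,
    kc_frac = kc_frac, k_SK = k_SK, sk_eq_nm = sk_eq_nm,
    dt = dt, seed = as.integer(seed),
    theta0_deg = theta0_deg,
    ring_radius_nm = ring_radius_nm,
    us = us
  )
  class(cfg) <- "axskel_config"
  cfg
}

#' @export
print.axskel_config <- function(x, ...) {
  cat("axskel model configuration:\n")
  cat(sprintf("  %d rings x %d beads, spacing %g nm (ring radius %.1f nm)\n",
              x$n_rings, x$particles_per_ring, x$ring_spacing_nm,
              x$ring_radius_nm))
  cat(sprintf("  %d filaments/gap x %d beads, junction eq %g nm\n",
              x$filaments_per_gap, x$beads_per_filament, x$junction_eq_nm))
  cat(sprintf("  k0=%g kA=%g eps/sigma^2, kb=%g kBT, kmt=%g kBT/sigma\n",
              x$k0, x$kA, x$kb_kBT, x$kmt_kBT_sigma))
  cat(sprintf("  dt=%g t_s, seed=%d\n", x$dt, x$seed))
  invisible(x)
}

#' Read / write a model configuration as a key:value text file
#'
#' The on-disk format is YAML with the same field names and units (nm,
#' kB*T, eps/sigma^2) as [model_config()]; the unit system is stored by its
#' defining scalars.
#'
#' @param path File path.
#' @param cfg An `axskel_config`.
#' @return `read_config()` returns an `axskel_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "axskel_config"))
  out <- cfg[setdiff(names(cfg), c("us", "theta0_deg", "ring_radius_nm"))]
  out$sigma_nm <- cfg$us$sigma_nm
  out$T_kelvin <- cfg$us$T_kelvin
  out$kT_over_eps <- cfg$us$kT_over_eps
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  us <- axon_units(sigma_nm = raw$sigma_nm %||% 4.45,
                   T_kelvin = raw$T_kelvin %||% 300,
                   kT_over_eps = raw$kT_over_eps %||% 0.03)
  raw$sigma_nm <- raw$T_kelvin <- raw$kT_over_eps <- NULL
  raw$us <- us
  do.call(model_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
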