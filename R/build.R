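#' @useDynLib axskel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# particle kind codes shared with the C++ engine
KIND_ACTIN <- 0L
KIND_SPECTRIN <- 1L
KIND_ANKYRIN <- 2L

# bead radii in nm (actin, spectrin, ankyrin/Nav complex)
KIND_RADII_NM <- c(17.5, 2.5, 12.5)

new_system <- function(pos, kind, cfg, clamped = NULL) {
  n <- nrow(pos)
  structure(list(
    pos = pos,
    vel = matrix(0, n, 3),
    kind = as.integer(kind),
    clamped = if (is.null(clamped)) rep(FALSE, n) else clamped,
    config = cfg
  ), class = "axskel_system")
}

#' @export
print.axskel_system <- function(x, ...) {
  tab <- table(factor(x$kind, levels = 0:2,
                      labels = c("actin", "spectrin", "ankyrin")))
  cat("axskel particle system:", nrow(x$pos), "particles (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
  invisible(x)
}

empty_topology <- function() {
  list(ss_bonds = matrix(0L, 0, 2), aa_bonds = matrix(0L, 0, 2),
       angles = matrix(0L, 0, 3), sk_bonds = matrix(0L, 0, 2),
       as_pairs = matrix(0L, 0, 2), as_state = integer(0),
       as_filament = integer(0),
       ring_id = integer(0), n_rings = 0L,
       filament_id = integer(0),
       theta0 = pi, dtheta_max = 0.3 * pi,
       confine = FALSE)
}

#' Build the axon membrane-skeleton geometry and topology
#'
#' Deterministically constructs the initial configuration: `n_rings` planar
#' actin rings (39 beads each, radius ~217 nm) in x-y planes spaced
#' `ring_spacing_nm` apart along z; in every inter-ring gap, 39 straight
#' spectrin filaments of 41 equally spaced beads running parallel to the
#' axis between angularly aligned junction actin beads (first/last bead
#' offset by `junction_eq_nm` from the actin centres); and one ankyrin bead
#' radially outward (at the ankyrin confinement radius) of each filament's
#' 20th bead. All actin-spectrin association pairs start intact.
#'
#' Coordinates are in reduced units (sigma); the axon axis is z.
#'
#' @param cfg An [model_config()] with `n_rings >= 2`.
#' @return A list with elements `system` (class `axskel_system`: positions,
#'   velocities, kinds, clamp flags) and `topology` (typed bond lists, ring
#'   angle triplets, breakable actin-spectrin pairs with live state, ring
#'   membership, FENE angle parameters, confinement flag).
#' @examples
#' ax <- build_axon(model_config(n_rings = 2))
#' nrow(ax$system$pos)  # 78 actin + 1599 spectrin + 39 ankyrin = 1716
#' @export
build_axon <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "axskel_config"))
  if (cfg$n_rings < 2) stop("an axon needs n_rings >= 2")
  us <- cfg$us
  np_ring <- cfg$particles_per_ring
  nf <- cfg$filaments_per_gap
  nb <- cfg$beads_per_filament
  n_gaps <- cfg$n_rings - 1L

  R <- nm_to_red(cfg$ring_radius_nm, us)
  d <- nm_to_red(cfg$ring_spacing_nm, us)
  joff <- nm_to_red(cfg$junction_eq_nm, us)
  rK <- nm_to_red(cfg$ankyrin_confine_radius_nm, us)

  n_actin <- cfg$n_rings * np_ring
  n_spec <- n_gaps * nf * nb
  n_ank <- n_gaps * nf
  n <- n_actin + n_spec + n_ank

  pos <- matrix(0, n, 3)
  kind <- integer(n)
  ring_id <- integer(n)
  filament_id <- integer(n)

  ang <- 2 * pi * (seq_len(np_ring) - 1) / np_ring
  # actin rings
  idx <- 1L
  for (g in seq_len(cfg$n_rings)) {
    z <- (g - 1L) * d
    rows <- idx:(idx + np_ring - 1L)
    pos[rows, 1] <- R * cos(ang)
    pos[rows, 2] <- R * sin(ang)
    pos[rows, 3] <- z
    kind[rows] <- KIND_ACTIN
    ring_id[rows] <- g
    idx <- idx + np_ring
  }
  actin_index <- function(g, f) (g - 1L) * np_ring + f  # f in 1..np_ring

  # spectrin filaments: angular index f attaches to actin bead f of both
  # bounding rings (no helical offset)
  ss_bonds <- matrix(0L, n_gaps * nf * (nb - 1L), 2)
  sk_bonds <- matrix(0L, n_gaps * nf, 2)
  as_pairs <- matrix(0L, n_gaps * nf * 2L, 2)
  as_fil <- integer(n_gaps * nf * 2L)
  ib <- ik <- ia <- 0L
  fil <- 0L
  for (g in seq_len(n_gaps)) {
    z0 <- (g - 1L) * d
    for (f in seq_len(nf)) {
      fil <- fil + 1L
      rows <- idx:(idx + nb - 1L)
      zs <- seq(z0 + joff, z0 + d - joff, length.out = nb)
      af <- 1L + ((f - 1L) %% np_ring)
      # zigzag layout: alternate beads are offset radially inward so that
      # consecutive beads sit at the full bond rest length even though the
      # junction-to-junction span is shorter than the chain contour; this
      # avoids starting deep inside the steric repulsion
      bond <- nm_to_red(cfg$spectrin_bond_eq_nm, us)
      dz <- if (nb > 1) zs[2] - zs[1] else 0
      amp <- sqrt(max(bond^2 - dz^2, 0))
      roff <- rep(c(0, -amp), length.out = nb)
      pos[rows, 1] <- (R + roff) * cos(ang[af])
      pos[rows, 2] <- (R + roff) * sin(ang[af])
      pos[rows, 3] <- zs
      kind[rows] <- KIND_SPECTRIN
      filament_id[rows] <- fil
      ss_bonds[ib + seq_len(nb - 1L), ] <- cbind(rows[-nb], rows[-1])
      ib <- ib + nb - 1L
      as_pairs[ia + 1L, ] <- c(actin_index(g, af), rows[1])
      as_pairs[ia + 2L, ] <- c(actin_index(g + 1L, af), rows[nb])
      as_fil[ia + 1L] <- fil
      as_fil[ia + 2L] <- fil
      ia <- ia + 2L
      idx <- idx + nb
    }
  }
  # ankyrin beads, outward of each filament's attach bead
  fil <- 0L
  spec_start <- n_actin
  for (g in seq_len(n_gaps)) {
    for (f in seq_len(nf)) {
      fil <- fil + 1L
      attach <- spec_start + (fil - 1L) * nb + cfg$ankyrin_attach_index
      af <- 1L + ((f - 1L) %% np_ring)
      pos[idx, 1] <- rK * cos(ang[af])
      pos[idx, 2] <- rK * sin(ang[af])
      pos[idx, 3] <- pos[attach, 3]
      kind[idx] <- KIND_ANKYRIN
      filament_id[idx] <- fil
      sk_bonds[ik + 1L, ] <- c(idx, attach)
      ik <- ik + 1L
      idx <- idx + 1L
    }
  }

  # ring bonds and angle triplets (cyclic)
  aa_bonds <- matrix(0L, cfg$n_rings * np_ring, 2)
  angles <- matrix(0L, cfg$n_rings * np_ring, 3)
  r <- 0L
  for (g in seq_len(cfg$n_rings)) {
    base <- (g - 1L) * np_ring
    j <- seq_len(np_ring)
    jn <- c(j[-1], j[1])
    jp <- c(j[np_ring], j[-np_ring])
    aa_bonds[r + j, ] <- cbind(base + j, base + jn)
    angles[r + j, ] <- cbind(base + jp, base + j, base + jn)
    r <- r + np_ring
  }

  theta0 <- pi * (np_ring - 2) / np_ring
  topo <- list(
    ss_bonds = ss_bonds, aa_bonds = aa_bonds, angles = angles,
    sk_bonds = sk_bonds, as_pairs = as_pairs,
    as_state = rep(1L, nrow(as_pairs)), as_filament = as_fil,
    ring_id = ring_id, n_rings = cfg$n_rings,
    filament_id = filament_id,
    theta0 = theta0, dtheta_max = cfg$dtheta_max_frac * theta0,
    confine = TRUE
  )
  list(system = new_system(pos, kind, cfg), topology = topo)
}

#' Build a free spectrin tetramer chain
#'
#' A single straight chain of `beads_per_filament` spectrin beads with
#' consecutive harmonic bonds at the 5 nm rest length, intra-chain steric
#' repulsion only; no rings, junctions, ankyrin, or confinement. Used to
#' measure the chain's thermal end-to-end distance and persistence length.
#'
#' @param cfg An [model_config()].
#' @return As [build_axon()]: list of `system` and `topology`.
#' @export
build_free_spectrin <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "axskel_config"))
  nb <- cfg$beads_per_filament
  a <- nm_to_red(cfg$spectrin_bond_eq_nm, cfg$us)
  pos <- cbind(0, 0, a * (seq_len(nb) - 1))
  topo <- empty_topology()
  if (nb > 1)
    topo$ss_bonds <- cbind(seq_len(nb - 1L), 2:nb)
  topo$ring_id <- integer(nb)
  topo$filament_id <- rep(1L, nb)
  list(system = new_system(pos, rep(KIND_SPECTRIN, nb), cfg),
       topology = topo)
}

#' Build a free straight actin-material filament
#'
#' A straight chain of actin-type beads (35 nm spacing) with the ring
#' force field: harmonic AA bonds (`kA`) and FENE bending about a straight
#' equilibrium angle (theta0 = 180 deg). With `clamped = TRUE` the first
#' two beads are immobilized, turning the chain into a thermal cantilever
#' for bending-rigidity measurements.
#'
#' @param n_beads Number of beads (>= 3).
#' @param clamped Clamp the first two beads?
#' @param cfg An [model_config()].
#' @return As [build_axon()].
#' @export
build_free_ring_filament <- function(n_beads, clamped = FALSE,
                                     cfg = model_config()) {
  stopifnot(inherits(cfg, "axskel_config"))
  if (n_beads < 3) stop("a bendable filament needs n_beads >= 3")
  n_beads <- as.integer(n_beads)
  a <- nm_to_red(cfg$actin_bead_diameter_nm, cfg$us)
  pos <- cbind(0, 0, a * (seq_len(n_beads) - 1))
  topo <- empty_topology()
  topo$aa_bonds <- cbind(seq_len(n_beads - 1L), 2:n_beads)
  topo$angles <- cbind(seq_len(n_beads - 2L), 2:(n_beads - 1L), 3:n_beads)
  topo$ring_id <- integer(n_beads)
  topo$filament_id <- rep(1L, n_beads)
  topo$theta0 <- pi
  topo$dtheta_max <- cfg$dtheta_max_frac * pi
  clamp <- rep(FALSE, n_beads)
  if (clamped) clamp[1:2] <- TRUE
  list(system = new_system(pos, rep(KIND_ACTIN, n_beads), cfg,
                           clamped = clamp),
       topology = topo)
}

#' Reduced-unit force-field parameter block
#'
#' Converts an `axskel_config` into the flat list of reduced-unit
#' parameters consumed by the C++ engine. Steric repulsions act between
#' all kind pairs, with shifted, purely repulsive Lennard-Jones potentials
#' cut at their minimum; cutoffs equal the additive contact distances
#' (S-S 5 nm, A-A 35 nm, S-K 15 nm, A-S 20 nm, A-K 30 nm, K-K 25 nm) and
#' well depths are eps/16 except the actin-spectrin core which uses eps
#' (matching the junction attraction whose curvature defines k0).
#'
#' @param cfg An [model_config()].
#' @param topology Optional topology (supplies the FENE angle parameters
#'   for free filaments, which use theta0 = 180 deg).
#' @return Named list of reduced parameters.
#' @keywords internal
reduced_params <- function(cfg, topology = NULL) {
  us <- cfg$us
  kT <- us$kT_over_eps
  nm <- function(x) nm_to_red(x, us)
  theta0 <- if (!is.null(topology)) topology$theta0 else
    pi * (cfg$particles_per_ring - 2) / cfg$particles_per_ring
  dtheta_max <- if (!is.null(topology)) topology$dtheta_max else
    cfg$dtheta_max_frac * theta0
  # steric contact cutoffs by unordered kind pair, nm
  contact_nm <- matrix(0, 3, 3)
  contact_nm[1, 1] <- cfg$actin_bead_diameter_nm           # A-A
  contact_nm[2, 2] <- cfg$spectrin_bond_eq_nm              # S-S
  contact_nm[3, 3] <- 2 * KIND_RADII_NM[3]                 # K-K
  contact_nm[1, 2] <- contact_nm[2, 1] <- cfg$junction_eq_nm   # A-S
  contact_nm[2, 3] <- contact_nm[3, 2] <- cfg$sk_eq_nm         # S-K
  contact_nm[1, 3] <- contact_nm[3, 1] <-
    KIND_RADII_NM[1] + KIND_RADII_NM[3]                    # A-K
  steric_cut <- nm(contact_nm)
  steric_scale <- steric_cut / 2^(1 / 6)
  steric_eps <- matrix(cfg$eps1_over_eps, 3, 3)
  steric_eps[1, 2] <- steric_eps[2, 1] <- 1

  as_sigma <- nm(cfg$junction_eq_nm) / 2^(1 / 6)
  deq <- nm(cfg$ring_spacing_nm)
  list(
    kT = kT, dt = cfg$dt,
    k0 = cfg$k0, req_ss = nm(cfg$spectrin_bond_eq_nm),
    kA = cfg$kA, req_aa = nm(cfg$actin_bead_diameter_nm),
    kSK = cfg$k_SK, req_sk = nm(cfg$sk_eq_nm),
    kb = cfg$kb_kBT * kT, theta0 = theta0, dtheta_max = dtheta_max,
    kmt = cfg$kmt_kBT_sigma * kT, deq = deq,
    ddmax = cfg$dd_max_frac * deq,
    kc = cfg$kc_frac * cfg$k0,
    r0_spectrin = nm(cfg$spectrin_confine_radius_nm),
    r0_ankyrin = nm(cfg$ankyrin_confine_radius_nm),
    as_sigma = as_sigma,
    as_r_inflex = (26 / 7)^(1 / 6) * as_sigma,
    as_r_capture = 2.5 * as_sigma,
    steric_scale = steric_scale, steric_eps = steric_eps,
    steric_cut = steric_cut,
    r_wall_S = nm(KIND_RADII_NM[2]), r_wall_A = nm(KIND_RADII_NM[1]),
    sk_gap_nm = cfg$sk_eq_nm
  )
}
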