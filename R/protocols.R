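#' Thermal end-to-end statistics of the free spectrin chain
#'
#' Equilibrates a free 41-bead spectrin tetramer and samples its
#' end-to-end distance over a long NVT run, then summarizes: the
#' root-mean-square end-to-end distance, a Gaussian fit (sample moments)
#' of the distance distribution, and the persistence length inferred from
#' the flexible-chain relation `<ree^2> = 2 lp Lc`.
#'
#' Sampling uses Andersen-style massive velocity collisions as the sole
#' thermostat (Hamiltonian dynamics between collisions): the
#' conformational modes of an isolated underdamped chain mix far too
#' slowly under purely deterministic dynamics to sample the canonical
#' ensemble on any practical run length, and collisions are canonical by
#' construction.
#'
#' @param cfg An [model_config()].
#' @param equil_steps Equilibration steps before sampling.
#' @param production_steps Sampling steps.
#' @param sample_stride Steps between end-to-end samples.
#' @param andersen_stride Massive-collision interval (steps).
#' @param seed RNG seed.
#' @return List with `ree_nm` (samples), `rms_ree_nm`, `mean_nm`,
#'   `sd_nm` (Gaussian fit by moments), `lp_nm`, and `contour_nm`.
#' @export
free_filament_stats <- function(cfg = model_config(),
                                equil_steps = 1e5,
                                production_steps = 3e6,
                                sample_stride = 500,
                                andersen_stride = 8000,
                                seed = cfg$seed) {
  b <- build_free_spectrin(cfg)
  nb <- cfg$beads_per_filament
  eq <- run_nvt(b$system, b$topology, n_steps = equil_steps, seed = seed,
                thermostat = FALSE, as_dynamic = FALSE,
                andersen_stride = andersen_stride)
  r <- run_nvt(eq$system, eq$topology, n_steps = production_steps,
               seed = seed + 1L, reinit_vel = FALSE, thermostat = FALSE,
               as_dynamic = FALSE, andersen_stride = andersen_stride,
               traj_stride = sample_stride, traj_idx = c(1L, nb))
  tr <- r$traj
  p1 <- tr[tr$particle == 1L, ]
  p2 <- tr[tr$particle == nb, ]
  ree2 <- (p1$x - p2$x)^2 + (p1$y - p2$y)^2 + (p1$z - p2$z)^2
  if (length(ree2) < 100)
    stop("too few end-to-end samples (< 100) for a distribution fit")
  sn <- cfg$us$sigma_nm
  ree_nm <- sqrt(ree2) * sn
  contour_nm <- (nb - 1) * cfg$spectrin_bond_eq_nm
  rms <- sqrt(mean(ree2)) * sn
  list(ree_nm = ree_nm,
       rms_ree_nm = rms,
       mean_nm = mean(ree_nm),
       sd_nm = stats::sd(ree_nm),
       lp_nm = rms^2 / (2 * contour_nm),
       contour_nm = contour_nm)
}

#' Bending rigidity of an actin-material filament from tip fluctuations
#'
#' Clamps the first two beads of a straight filament carrying the
#' actin-ring force field (harmonic bonds `kA`, FENE bending `kb` about a
#' straight equilibrium) and records the thermal transverse displacement
#' of the free tip. For a clamped cantilever of length L,
#' `<du^2> = L^3 kB T / (3 kappa)` per transverse direction, which is
#' inverted for the bending rigidity `kappa`.
#'
#' @param n_beads Filament beads (default 13: a ~420 nm cantilever).
#' @param cfg An [model_config()].
#' @param production_steps Sampling steps.
#' @param sample_stride Steps between tip samples.
#' @param andersen_stride Massive-collision interval.
#' @param seed RNG seed.
#' @return List with `kappa_Nm2` (bending rigidity, N m^2),
#'   `kappa_reduced` (eps*sigma), `du2_mean` (per-direction transverse
#'   tip variance, sigma^2) and `L_nm` (flexible length).
#' @export
bending_rigidity <- function(n_beads = 13, cfg = model_config(),
                             production_steps = 2e6,
                             sample_stride = 500,
                             andersen_stride = 8000,
                             seed = cfg$seed) {
  b <- build_free_ring_filament(n_beads, clamped = TRUE, cfg = cfg)
  eq <- run_nvt(b$system, b$topology, n_steps = 1e5, seed = seed,
                thermostat = FALSE, as_dynamic = FALSE,
                andersen_stride = andersen_stride)
  r <- run_nvt(eq$system, eq$topology, n_steps = production_steps,
               seed = seed + 1L, reinit_vel = FALSE, thermostat = FALSE,
               as_dynamic = FALSE, andersen_stride = andersen_stride,
               traj_stride = sample_stride, traj_idx = n_beads)
  tr <- r$traj
  if (nrow(tr) < 100) stop("too few tip samples for a variance estimate")
  # clamp axis is z; transverse = (x, y); per-direction variance
  du2 <- (stats::var(tr$x) + stats::var(tr$y)) / 2
  us <- cfg$us
  a <- nm_to_red(cfg$actin_bead_diameter_nm, us)
  L <- (n_beads - 2) * a  # flexible length beyond the clamp
  kT <- us$kT_over_eps
  kappa_red <- L^3 * kT / (3 * du2)  # eps * sigma
  kappa_SI <- kappa_red * us$epsilon_J * us$sigma_m
  list(kappa_Nm2 = kappa_SI, kappa_reduced = kappa_red,
       du2_mean = du2, L_nm = red_to_nm(L, us))
}

#' Radial-expansion stiffness of the axon membrane skeleton
#'
#' The in-silico analogue of inflating the axon: an internal cylindrical
#' repulsive wall is ramped up to the skeleton radius (217 nm) and then
#' expanded outward in `increments` steps of `dr_nm`, each increment
#' taking `transition` steps followed by `equil_steps` relaxation and a
#' `measure` step window in which the outward wall force is recorded every
#' step, split into 80 nm stripes centred on the actin rings, the
#' complementary 105 nm stripes between rings, and their union. Stripe
#' pressures (total force / lateral stripe area at the current wall
#' radius) are averaged per increment, the slope of mean pressure versus
#' radial expansion is fitted by ordinary least squares, and thin-walled
#' cylindrical shell theory `E = p R^2 / (delta H)` converts the slopes
#' into Young's moduli with R = 217 nm and shell thickness H = 10 nm.
#'
#' While the wall is active the bilayer confinement radii follow the wall
#' (`conf_track`): the confinement stands in for the bilayer, which must
#' expand with the imposed inflation; pinning it at the rest radius would
#' make the measured pressure reflect the confinement springs instead of
#' the skeleton.
#'
#' @param build An equilibrated `list(system, topology)` (see
#'   [equilibrate()]); 185 nm ring spacing assumed for stripe widths.
#' @param increments Number of expansion increments.
#' @param dr_nm Radial increment, nm.
#' @param transition,equil_steps,measure Steps per increment phase.
#' @param ramp_in Steps over which the wall radius is first ramped from
#'   well inside the skeleton up to `r_start_nm`.
#' @param r_start_nm Wall radius at the start of the measured expansion.
#' @param shell_H_nm Shell thickness used in the inversion.
#' @param ring_half_width_nm Half-width of ring stripes (40 = 80 nm bands).
#' @param conf_track Confinement follows the wall (default TRUE).
#' @param seed RNG seed.
#' @return An `axskel_stiffness` object: `increments` data frame (wall
#'   radius, mean and sd of the three stripe pressures in reduced units),
#'   fitted slopes, `E_ring_kPa`, `E_between_kPa`, `E_avg_kPa`, fit R^2,
#'   and the count of junction pairs broken during the run.
#' @export
radial_expansion <- function(build, increments = 20, dr_nm = 0.5,
                             transition = 1000, equil_steps = 1000,
                             measure = 8000, ramp_in = 30000,
                             r_start_nm = 217, shell_H_nm = 10,
                             ring_half_width_nm = 40,
                             conf_track = TRUE, seed = NULL) {
  sys <- build$system; topo <- build$topology
  cfg <- sys$config
  if (is.null(seed)) seed <- cfg$seed + 100L
  us <- cfg$us
  nm <- function(x) nm_to_red(x, us)
  rc0 <- nm(r_start_nm)
  # ramp the wall in from well inside the skeleton so contact develops
  # gradually instead of starting deep inside the repulsion
  ramp_from <- nm(r_start_nm - 32)
  r <- run_nvt(sys, topo, n_steps = ramp_in, seed = seed,
               reinit_vel = FALSE,
               wall_rc = seq(ramp_from, rc0, length.out = ramp_in),
               conf_track = conf_track, cap_force = 1000,
               ring_half_width_nm = ring_half_width_nm)
  per <- transition + equil_steps + measure
  sched <- numeric(increments * per)
  mask <- logical(increments * per)
  rc <- rc0
  incr <- nm(dr_nm)
  for (i in seq_len(increments)) {
    o <- (i - 1) * per
    sched[o + seq_len(transition)] <- rc + incr * seq_len(transition) / transition
    rc <- rc + incr
    sched[o + transition + seq_len(equil_steps + measure)] <- rc
    mask[o + transition + equil_steps + seq_len(measure)] <- TRUE
  }
  r2 <- run_nvt(r$system, r$topology, n_steps = length(sched),
                seed = seed + 1L, reinit_vel = FALSE,
                wall_rc = sched, conf_track = conf_track,
                measure_steps = mask,
                ring_half_width_nm = ring_half_width_nm)
  pr <- r2$pressure
  pr$inc <- findInterval(pr$step - 1L, (0:increments) * per)
  n_r <- topo$n_rings
  w_ring <- 2 * nm(ring_half_width_nm)
  w_btw <- nm(cfg$ring_spacing_nm) - w_ring
  res <- do.call(rbind, lapply(split(pr, pr$inc), function(d) {
    a_ring <- 2 * pi * d$r_c[1] * w_ring * n_r
    a_btw <- 2 * pi * d$r_c[1] * w_btw * (n_r - 1)
    data.frame(inc = d$inc[1], r_c = d$r_c[1],
               p_ring = mean(d$F_ring) / a_ring,
               p_ring_sd = stats::sd(d$F_ring) / a_ring,
               p_between = mean(d$F_between) / a_btw,
               p_between_sd = stats::sd(d$F_between) / a_btw,
               p_all = mean(d$F_all) / (a_ring + a_btw),
               p_all_sd = stats::sd(d$F_all) / (a_ring + a_btw))
  }))
  res <- res[order(res$inc), ]
  delta <- res$r_c - rc0
  R <- nm(217); H <- nm(shell_H_nm)
  p_to_kPa <- to_SI(1, "pressure", us) / 1000
  fit1 <- function(p) {
    m <- stats::lm(p ~ delta)
    list(slope = unname(stats::coef(m)[2]),
         r2 = summary(m)$r.squared,
         E_kPa = unname(stats::coef(m)[2]) * R^2 / H * p_to_kPa)
  }
  fr <- fit1(res$p_ring); fb <- fit1(res$p_between); fa <- fit1(res$p_all)
  out <- list(increments = res,
              E_ring_kPa = fr$E_kPa, E_between_kPa = fb$E_kPa,
              E_avg_kPa = fa$E_kPa,
              slope_ring = fr$slope, slope_between = fb$slope,
              slope_all = fa$slope,
              r2_ring = fr$r2, r2_between = fb$r2, r2_all = fa$r2,
              w_ring_nm = red_to_nm(w_ring, us),
              w_between_nm = red_to_nm(w_btw, us),
              broken = sum(r2$topology$as_state == 0),
              system = r2$system, topology = r2$topology)
  class(out) <- "axskel_stiffness"
  out
}

#' @export
print.axskel_stiffness <- function(x, ...) {
  cat("Radial-expansion stiffness (shell inversion, R = 217 nm, H = 10 nm):\n")
  cat(sprintf("  E_ring    = %.4g kPa (R^2 = %.3f)\n", x$E_ring_kPa, x$r2_ring))
  cat(sprintf("  E_between = %.4g kPa (R^2 = %.3f)\n", x$E_between_kPa,
              x$r2_between))
  cat(sprintf("  E_avg     = %.4g kPa (R^2 = %.3f)\n", x$E_avg_kPa, x$r2_all))
  if (x$broken > 0)
    cat("  warning:", x$broken, "junction pairs broken during expansion\n")
  invisible(x)
}

#' Thermal motion statistics of ankyrin/Nav particles
#'
#' Records ankyrin positions every `stride` steps over a long NVT run of
#' an equilibrated axon and summarizes (i) the average planar trajectory
#' radius: per ankyrin, the RMS deviation of its samples from its mean
#' position in the local membrane plane spanned by the axial (z) and
#' circumferential-arc directions, averaged over ankyrins; (ii) the
#' longitudinal order statistic: the pooled normalized deviations
#' `d(z)/Lc`, where `d(z)` is each sample's z-deviation from that
#' ankyrin's mean and `Lc` is the measured mean z-spacing between
#' consecutive ankyrin rows, with `s` its standard deviation.
#'
#' @param build An equilibrated `list(system, topology)`.
#' @param production_steps Sampling steps (must be >= 10 strides).
#' @param stride Steps between position samples.
#' @param seed RNG seed.
#' @return An `axskel_ankyrin` object: `radius_nm`, `Lc_nm`, `s`,
#'   per-ankyrin radii, pooled `dz_over_Lc` samples, and the trajectory.
#' @export
ankyrin_motion <- function(build, production_steps = 1e6, stride = 1e4,
                           seed = NULL) {
  sys <- build$system; topo <- build$topology
  cfg <- sys$config
  if (is.null(seed)) seed <- cfg$seed + 200L
  if (production_steps < 10 * stride)
    stop("production_steps must cover at least 10 sampling strides")
  ank <- which(sys$kind == KIND_ANKYRIN)
  r <- run_nvt(sys, topo, n_steps = production_steps, seed = seed,
               reinit_vel = FALSE, traj_stride = stride, traj_idx = ank)
  tr <- r$traj
  us <- cfg$us
  per <- split(tr, tr$particle)
  rad <- vapply(per, function(s) {
    phi <- atan2(s$y, s$x)
    phim <- atan2(mean(sin(phi)), mean(cos(phi)))
    dphi <- ((phi - phim + pi) %% (2 * pi)) - pi
    arc <- mean(sqrt(s$x^2 + s$y^2)) * dphi
    dz <- s$z - mean(s$z)
    sqrt(mean(arc^2 + dz^2))
  }, numeric(1))
  zm <- vapply(per, function(s) mean(s$z), numeric(1))
  # consecutive ankyrin rows along z: one row per inter-ring gap
  gap_of <- topo$filament_id[ank]
  n_gaps <- topo$n_rings - 1L
  gap_id <- ceiling(gap_of / cfg$filaments_per_gap)
  row_z <- tapply(zm, gap_id, mean)
  Lc <- if (n_gaps >= 2) mean(diff(sort(row_z))) else
    nm_to_red(cfg$ring_spacing_nm, us)
  dz_pool <- unlist(lapply(per, function(s) s$z - mean(s$z)),
                    use.names = FALSE)
  out <- list(radius_nm = mean(rad) * us$sigma_nm,
              radii_nm = rad * us$sigma_nm,
              Lc_nm = Lc * us$sigma_nm,
              dz_over_Lc = dz_pool / Lc,
              s = stats::sd(dz_pool / Lc),
              traj = tr,
              broken = sum(r$topology$as_state == 0))
  class(out) <- "axskel_ankyrin"
  out
}

#' @export
print.axskel_ankyrin <- function(x, ...) {
  cat("Ankyrin thermal motion:\n")
  cat(sprintf("  mean planar trajectory radius = %.3g nm\n", x$radius_nm))
  cat(sprintf("  mean ankyrin z-spacing Lc = %.4g nm\n", x$Lc_nm))
  cat(sprintf("  std of pooled d(z)/Lc: s = %.3g\n", x$s))
  invisible(x)
}

#' Laceration and re-association of spectrin filaments
#'
#' Severs `n_severed` angularly contiguous spectrin filaments in one
#' inter-ring gap by forcing one of their two junctions to the broken
#' state, lets the lacerated network relax with recapture
#' suppressed for the severed pairs (`evolve` steps), then re-enables
#' recapture at the capture radius `2.5 * (4 sigma)` and watches for
#' `watch` steps, recording which severed filaments re-associate with
#' their original junction.
#'
#' @param build An equilibrated `list(system, topology)`.
#' @param n_severed Number of filaments to sever (of the 39 in the gap).
#' @param gap Which inter-ring gap to lacerate.
#' @param evolve_steps Relaxation steps with recapture suppressed.
#' @param watch_steps Steps with recapture re-enabled.
#' @param log_stride Steps between junction-state snapshots.
#' @param seed RNG seed.
#' @return An `axskel_laceration` object: severed pair indices, a
#'   reconnection time series (`step`, `n_reconnected`, `fraction`), and
#'   `fraction_at(steps)` checkpoints stored as `checkpoints`.
#' @export
lacerate_and_watch <- function(build, n_severed = 15, gap = 1,
                               evolve_steps = 1e4, watch_steps = 5e4,
                               log_stride = 500, seed = NULL) {
  sys <- build$system; topo <- build$topology
  cfg <- sys$config
  if (is.null(seed)) seed <- cfg$seed + 300L
  nf <- cfg$filaments_per_gap
  stopifnot(n_severed >= 0, n_severed <= nf, gap <= topo$n_rings - 1L)
  fil <- (gap - 1L) * nf + seq_len(n_severed)
  # sever each filament at one end only: the junction on the second
  # bounding ring of the gap. In a model with a following gap that ring
  # is anchored by another full set of filaments, so the vacated
  # junctions stay in place while the severed chains recoil
  sever_pairs <- which(topo$as_filament %in% fil &
                         topo$ring_id[topo$as_pairs[, 1]] == gap + 1L)
  topo$as_state[sever_pairs] <- 0L
  suppress <- rep(FALSE, length(topo$as_state))
  suppress[sever_pairs] <- TRUE
  r1 <- run_nvt(sys, topo, n_steps = evolve_steps, seed = seed,
                reinit_vel = FALSE, suppress_capture = suppress)
  r2 <- run_nvt(r1$system, r1$topology, n_steps = watch_steps,
                seed = seed + 1L, reinit_vel = FALSE,
                as_log_stride = log_stride)
  lg <- r2$as_log
  if (n_severed == 0) {
    series <- data.frame(step = lg[, 1], n_reconnected = 0, fraction = 1)
  } else {
    nrec <- rowSums(lg[, 1 + sever_pairs, drop = FALSE] == 1L)
    series <- data.frame(step = lg[, 1], n_reconnected = nrec,
                         fraction = nrec / length(sever_pairs))
  }
  out <- list(severed_pairs = sever_pairs,
              severed_filaments = fil,
              series = series,
              fraction_final = series$fraction[nrow(series)],
              system = r2$system, topology = r2$topology)
  class(out) <- "axskel_laceration"
  out
}

#' @export
print.axskel_laceration <- function(x, ...) {
  cat(sprintf("Laceration: %d severed junctions; %.0f%% re-associated by step %d\n",
              length(x$severed_pairs), 100 * x$fraction_final,
              max(x$series$step)))
  invisible(x)
}

#' Fraction of severed junctions reconnected at a given watch step
#' @param x An `axskel_laceration`.
#' @param step Watch-phase step (steps after recapture was re-enabled).
#' @return Fraction in \[0, 1\].
#' @export
fraction_reconnected_at <- function(x, step) {
  s <- x$series
  s$fraction[max(which(s$step <= step))]
}

#' Nav channel density implied by the skeleton geometry
#'
#' One Nav channel rides on each ankyrin (one per spectrin tetramer), so
#' the areal density is the ankyrin count divided by the lateral membrane
#' area `pi * D * L` with D the ring diameter (~434 nm) and L the axon
#' length covered by the inter-ring gaps.
#'
#' @param build A built axon `list(system, topology)`.
#' @return Channels per square micrometre.
#' @export
channel_density <- function(build) {
  cfg <- build$system$config
  n_ank <- sum(build$system$kind == KIND_ANKYRIN)
  if (n_ank == 0) return(0)
  D_um <- 2 * cfg$ring_radius_nm / 1000
  L_um <- (cfg$n_rings - 1) * cfg$ring_spacing_nm / 1000
  n_ank / (pi * D_um * L_um)
}
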