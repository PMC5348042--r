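params <- reduced_params(model_config())

test_that("harmonic bond follows Hooke's law in reduced units", {
  hb <- harmonic_bond(params$req_ss, 3.56, params$req_ss)
  expect_equal(hb$energy, 0)
  expect_equal(hb$force, 0)
  hb <- harmonic_bond(params$req_ss + 1, 3.56, params$req_ss)
  expect_equal(hb$energy, 1.78)
  expect_equal(hb$force, -3.56)
})

test_that("steric repulsion is shifted, truncated and purely repulsive", {
  s <- 1
  cut <- 2^(1 / 6)
  at_cut <- repulsive_lj(cut, 1 / 16, s)
  expect_equal(at_cut$energy, 0)
  expect_equal(at_cut$force, 0)
  beyond <- repulsive_lj(2, 1 / 16, s)
  expect_equal(beyond$energy, 0)
  expect_equal(beyond$force, 0)
  r <- seq(0.8, cut, by = 0.01)
  inside <- repulsive_lj(r, 1 / 16, s)
  expect_true(all(inside$energy >= 0))
  expect_true(all(inside$force >= 0))
  expect_true(all(diff(inside$energy) <= 0))  # monotone decreasing to 0
  # near-contact forces raise the capped flag used for step rejection
  expect_true(repulsive_lj(0.3, 1, s)$capped)
})

test_that("eps/16 repulsion curvature at contact equals the bond constant k0", {
  # d2U/dr2 at the minimum of the eps/16 LJ is 36*2^(2/3)*eps1/s^2 ~ 3.57,
  # the stated origin of k0 = 3.56
  s <- 1
  h <- 1e-4
  r0 <- 2^(1 / 6) * s
  u <- function(r) repulsive_lj(r, 1 / 16, s)$energy
  # one-sided stencil: the potential is truncated at its minimum, so the
  # curvature must be taken from inside the cutoff
  curv <- (u(r0 - 2 * h) - 2 * u(r0 - h) + u(r0)) / h^2
  expect_equal(curv, 36 * 2^(2 / 3) / 16, tolerance = 2e-3)
  expect_equal(36 * 2^(2 / 3) / 16, 3.56, tolerance = 5e-3)
})

test_that("FENE bending is harmonic for small angles and diverges at the cap", {
  kb <- 3500 * 0.03  # eps
  th0 <- params$theta0
  dmax <- 0.894
  expect_equal(fene_angle(th0, kb, th0, dmax)$energy, 0)
  expect_equal(fene_angle(th0, kb, th0, dmax)$torque, 0)
  # Taylor oracle: U ~ (kb/dmax) * dth^2 / 2 (kb in kBT -> energy in kBT)
  dth <- 0.01
  e_kBT <- fene_angle(th0 + dth, 3500 * 0.03, th0, dmax)$energy / 0.03
  expect_equal(e_kBT, 0.5 * (3500 / dmax) * dth^2, tolerance = 1e-2)
  expect_equal(e_kBT, 0.196, tolerance = 1.5e-2)
  # divergence at the maximum deformation
  e99 <- fene_angle(th0 + 0.999999 * dmax, kb, th0, dmax)$energy
  expect_gt(e99, fene_angle(th0 + 0.9 * dmax, kb, th0, dmax)$energy * 5)
  expect_error(fene_angle(th0 + dmax, kb, th0, dmax), "FENE")
})

test_that("junction attraction has the printed equilibrium, inflexion and capture", {
  us <- axon_units()
  eq_nm <- 2^(1 / 6) * params$as_sigma * us$sigma_nm
  expect_equal(eq_nm, 20, tolerance = 1e-6)
  expect_equal(params$as_r_inflex * us$sigma_nm, (26 / 7)^(1 / 6) * 17.82,
               tolerance = 1e-3)
  expect_equal(params$as_r_inflex * us$sigma_nm, 22.17, tolerance = 1e-3)
  expect_equal(params$as_r_capture * us$sigma_nm, 44.5, tolerance = 2e-3)
  at_eq <- as_attraction(2^(1 / 6) * params$as_sigma, "intact", params)
  expect_equal(at_eq$energy, -1)
  expect_equal(at_eq$force, 0, tolerance = 1e-12)
  expect_equal(at_eq$new_state, "intact")
})

test_that("junction state machine cycles break -> stay broken -> recapture", {
  us <- axon_units()
  nm <- function(x) x / us$sigma_nm
  # intact at equilibrium stays intact
  expect_equal(as_attraction(nm(20), "intact", params)$new_state, "intact")
  # crossing the inflexion breaks it
  expect_equal(as_attraction(nm(23), "intact", params)$new_state, "broken")
  # far beyond capture: stays broken with zero interaction
  far <- as_attraction(nm(50), "broken", params)
  expect_equal(far$new_state, "broken")
  expect_equal(far$energy, 0)
  expect_equal(far$force, 0)
  # inside the capture radius: reforms
  expect_equal(as_attraction(nm(40), "broken", params)$new_state, "intact")
  # hysteresis ordering: equilibrium < inflexion < capture
  expect_lt(2^(1 / 6) * params$as_sigma, params$as_r_inflex)
  expect_lt(params$as_r_inflex, params$as_r_capture)
  # broken pairs keep a repulsive core below contact
  core <- as_attraction(nm(15), "broken", params)
  expect_equal(core$new_state, "intact")  # 15 nm < capture
  deep <- as_attraction(nm(10), "broken",
                        modifyList(params, list(as_r_capture = nm(5))))
  expect_equal(deep$new_state, "broken")
  expect_gt(deep$force, 0)
})

test_that("inter-ring coupling is a FENE restraint on centre distances", {
  deq <- params$deq
  rc <- ring_coupling(c(0, deq), params$kmt, deq, params$ddmax)
  expect_equal(rc$energy, 0)
  expect_equal(unname(rc$force_per_bead[, "fz"]), c(0, 0))
  # small-deformation spring constant kmt/ddmax via central differences
  h <- 1e-4
  e <- function(d) ring_coupling(c(0, d), params$kmt, deq,
                                 params$ddmax)$energy
  curv <- (e(deq - h) - 2 * e(deq) + e(deq + h)) / h^2
  expect_equal(curv, params$kmt / params$ddmax, tolerance = 1e-6)
  expect_error(ring_coupling(c(0, deq + params$ddmax), params$kmt, deq,
                             params$ddmax), "FENE")
})

test_that("confinement is one-sided for spectrin, two-sided for ankyrin", {
  us <- axon_units()
  nm <- function(x) x / us$sigma_nm
  inside <- confinement(nm(200), "spectrin", params)
  expect_equal(inside$energy, 0)
  expect_equal(inside$force, 0)
  out <- confinement(nm(218), "spectrin", params)
  expect_equal(out$force, -0.1 * 3.56 * nm(1))  # restoring, inward
  at_r0 <- confinement(nm(232), "ankyrin", params)
  expect_equal(at_r0$force, 0)
  in_k <- confinement(nm(230), "ankyrin", params)
  expect_gt(in_k$force, 0)  # pushed back outward
})

test_that("expansion wall vanishes at contact, beyond cutoff, and when off", {
  us <- axon_units()
  nm <- function(x) x / us$sigma_nm
  rc <- nm(217)
  s_at <- expansion_wall(rc + params$r_wall_S, "spectrin", rc, params)
  expect_equal(s_at$energy, 0, tolerance = 1e-12)
  expect_equal(s_at$force, 0, tolerance = 1e-12)
  a_at <- expansion_wall(rc + params$r_wall_A, "actin", rc, params)
  expect_equal(a_at$force, 0, tolerance = 1e-12)
  off <- expansion_wall(nm(210), "spectrin", NULL, params)
  expect_equal(off$energy, 0)
  expect_equal(off$force, 0)
  inside <- expansion_wall(rc, "spectrin", rc, params)
  expect_gt(inside$force, 0)  # outward push
})

test_that("analytic forces match central-difference energy gradients", {
  set.seed(7)
  # free spectrin chain, perturbed
  b <- build_free_spectrin(model_config())
  b$system$pos <- b$system$pos + matrix(rnorm(41 * 3, 0, 0.05), 41)
  tf <- total_forces(b$system, b$topology)
  fd <- fd_forces(b$system, b$topology, 1:41)
  expect_lt(max(abs(fd - tf$forces)) / max(1, max(abs(tf$forces))), 1e-6)
  # small axon with wall active and junctions present
  cfg <- model_config(n_rings = 2, filaments_per_gap = 2)
  ax <- build_axon(cfg)
  ax$system$pos <- ax$system$pos +
    matrix(rnorm(length(ax$system$pos), 0, 0.03), nrow(ax$system$pos))
  # wall radius chosen so no particle sits in the capped near-singular zone
  rc <- 210 / cfg$us$sigma_nm
  tf <- total_forces(ax$system, ax$topology, wall_rc = rc)
  idx <- sample(nrow(ax$system$pos), 25)
  fd <- fd_forces(ax$system, ax$topology, idx, wall_rc = rc)
  scale <- max(1, max(abs(tf$forces[idx, ])))
  expect_lt(max(abs(fd - tf$forces[idx, ])) / scale, 1e-6)
  # free ring filament (FENE angles at theta0 = pi, perturbed off-axis)
  fil <- build_free_ring_filament(8)
  fil$system$pos <- fil$system$pos +
    matrix(rnorm(24, 0, 0.3), 8)
  tf <- total_forces(fil$system, fil$topology)
  fd <- fd_forces(fil$system, fil$topology, 1:8, h = 1e-5)
  expect_lt(max(abs(fd - tf$forces)) / max(1, max(abs(tf$forces))), 1e-6)
})

test_that("internal forces obey Newton's third law", {
  set.seed(11)
  b <- build_free_spectrin(model_config())
  b$system$pos <- b$system$pos + matrix(rnorm(123, 0, 0.1), 41)
  tf <- total_forces(b$system, b$topology)
  expect_lt(max(abs(colSums(tf$forces))), 1e-10)
  fil <- build_free_ring_filament(9)
  fil$system$pos <- fil$system$pos + matrix(rnorm(27, 0, 0.2), 9)
  tf <- total_forces(fil$system, fil$topology)
  expect_lt(max(abs(colSums(tf$forces))), 1e-10)
})

test_that("energy breakdown terms are non-negative where repulsive-only", {
  set.seed(13)
  ax <- build_axon(model_config(n_rings = 2, filaments_per_gap = 3))
  ax$system$pos <- ax$system$pos +
    matrix(rnorm(length(ax$system$pos), 0, 0.05), nrow(ax$system$pos))
  bd <- total_forces(ax$system, ax$topology,
                     wall_rc = 217 / axon_units()$sigma_nm)$breakdown
  for (term in c("ss", "aa", "sk", "angle", "mt", "steric", "confine",
                 "wall"))
    expect_gte(bd[[term]], 0)
})
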