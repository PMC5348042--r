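two_bead <- function() {
  cfg <- model_config(beads_per_filament = 2, ankyrin_attach_index = 1)
  build_free_spectrin(cfg)
}

test_that("a force-free particle moves uniformly", {
  b <- two_bead()
  b$topology$ss_bonds <- matrix(0L, 0, 2)
  b$system$pos[2, ] <- c(50, 0, 0)           # out of steric range
  b$system$vel[1, ] <- c(0.1, 0.02, -0.03)
  r <- run_nvt(b$system, b$topology, n_steps = 1000, thermostat = FALSE,
               reinit_vel = FALSE, as_dynamic = FALSE)
  expect_equal(r$system$pos[1, ], c(0.1, 0.02, -0.03) * 10,
               tolerance = 1e-12)
})

test_that("unthermostatted dynamics conserves energy", {
  b <- two_bead()
  b$system$pos[2, 3] <- b$system$pos[2, 3] + 0.2
  r <- run_nvt(b$system, b$topology, n_steps = 1e4, thermostat = FALSE,
               reinit_vel = FALSE, as_dynamic = FALSE, thermo_stride = 10)
  E <- r$thermo$E_pot + r$thermo$E_kin
  expect_lt((max(E) - min(E)) / max(abs(E)), 1e-3)
  # thermalized 41-bead chain
  chain <- build_free_spectrin(model_config())
  warm <- run_nvt(chain$system, chain$topology, n_steps = 5000, seed = 5,
                  as_dynamic = FALSE)
  r2 <- run_nvt(warm$system, warm$topology, n_steps = 1e4,
                thermostat = FALSE, reinit_vel = FALSE, as_dynamic = FALSE,
                thermo_stride = 10)
  E2 <- r2$thermo$E_pot + r2$thermo$E_kin
  expect_lt((max(E2) - min(E2)) / max(abs(E2)), 1e-3)
})

test_that("two-bead oscillation period matches the two-branch oracle", {
  # small-amplitude bond oscillation: compression half-cycle feels the
  # bond spring plus the steric curvature (itself ~k0), extension only the
  # spring; the period is the mean of the two harmonic half-periods with
  # reduced mass 1/2
  b <- two_bead()
  b$system$pos[2, 3] <- b$system$pos[2, 3] + 0.02
  r <- run_nvt(b$system, b$topology, n_steps = 8192, thermostat = FALSE,
               reinit_vel = FALSE, as_dynamic = FALSE,
               traj_stride = 1, traj_idx = 1:2)
  z <- r$traj$z[r$traj$particle == 2] - r$traj$z[r$traj$particle == 1]
  dev <- z - mean(z)
  crossings <- sum(diff(sign(dev)) != 0)
  period_steps <- 2 * length(dev) / crossings
  m_red <- 0.5
  k_ext <- 3.56
  k_cmp <- 3.56 + 36 * 2^(2 / 3) / 16 * (2^(1 / 6) / reduced_params(
    model_config())$req_ss)^2  # steric curvature at the bond rest length
  T_pred <- pi * (sqrt(m_red / k_ext) + sqrt(m_red / k_cmp)) / 0.01
  expect_equal(period_steps, T_pred, tolerance = 0.01)
})

test_that("Berendsen thermostat holds the reduced temperature at 0.03", {
  chain <- build_free_spectrin(model_config())
  r <- run_nvt(chain$system, chain$topology, n_steps = 2e5, seed = 9,
               as_dynamic = FALSE, thermo_stride = 100)
  kT <- r$thermo$kT_inst[r$thermo$step > 2e4]
  expect_equal(mean(kT), 0.03, tolerance = 0.02)
  expect_lt(abs(mean(kT) - 0.03), 1e-3)
})

test_that("trajectories are a deterministic function of the seed", {
  chain <- build_free_spectrin(model_config())
  r1 <- run_nvt(chain$system, chain$topology, n_steps = 2000, seed = 42,
                as_dynamic = FALSE)
  r2 <- run_nvt(chain$system, chain$topology, n_steps = 2000, seed = 42,
                as_dynamic = FALSE)
  expect_identical(r1$system$pos, r2$system$pos)
  expect_identical(r1$system$vel, r2$system$vel)
  r3 <- run_nvt(chain$system, chain$topology, n_steps = 2000, seed = 43,
                as_dynamic = FALSE)
  expect_false(identical(r1$system$pos, r3$system$pos))
})

test_that("a zero-step run returns the input state", {
  chain <- build_free_spectrin(model_config())
  r <- run_nvt(chain$system, chain$topology, n_steps = 0)
  expect_identical(r$system$pos, chain$system$pos)
})

test_that("clamped particles stay put and are excluded from the bath", {
  b <- build_free_ring_filament(6, clamped = TRUE)
  r <- run_nvt(b$system, b$topology, n_steps = 5000, seed = 3,
               as_dynamic = FALSE, thermo_stride = 100)
  expect_identical(r$system$pos[1:2, ], b$system$pos[1:2, ])
  expect_true(all(r$system$vel[1:2, ] == 0))
  kT <- r$thermo$kT_inst[r$thermo$step > 1000]
  expect_equal(mean(kT), 0.03, tolerance = 0.1)
})

test_that("ring-spacing schedule moves ring centres to a new target", {
  cfg <- model_config(n_rings = 2, filaments_per_gap = 2)
  ax <- build_axon(cfg)
  us <- cfg$us
  target <- 180 / us$sigma_nm
  sched <- seq(185 / us$sigma_nm, target, length.out = 20000)
  r <- run_nvt(ax$system, ax$topology, n_steps = 20000, seed = 4,
               cap_force = 1000, deq_schedule = sched)
  z <- r$system$pos[, 3]
  rid <- r$topology$ring_id
  d <- mean(z[rid == 2]) - mean(z[rid == 1])
  expect_equal(d * us$sigma_nm, 180, tolerance = 0.03)
})
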