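test_that("configuration derives ring geometry from bead counts", {
  cfg <- model_config()
  expect_equal(cfg$theta0_deg, 180 * 37 / 39)
  expect_equal(cfg$theta0_deg, 170.77, tolerance = 1e-4)
  # 39 chords of 35 nm close a circle of diameter ~434-435 nm
  expect_equal(2 * cfg$ring_radius_nm, 435, tolerance = 3e-3)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(model_config(n_rings = 0), "positive")
  expect_error(model_config(k0 = -1), "positive")
  expect_error(model_config(junction_eq_nm = 12), "junction_eq_nm")
  expect_silent(model_config(junction_eq_nm = 12, junction_override = TRUE))
  expect_silent(model_config(junction_eq_nm = 15))
  expect_error(model_config(ankyrin_attach_index = 50), "out of range")
})

test_that("configuration survives a YAML round trip", {
  cfg <- model_config(n_rings = 5, ring_spacing_nm = 110, seed = 42)
  path <- tempfile(fileext = ".yml")
  on.exit(unlink(path))
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$n_rings, 5L)
  expect_equal(cfg2$ring_spacing_nm, 110)
  expect_equal(cfg2$seed, 42L)
  expect_equal(cfg2$theta0_deg, cfg$theta0_deg)
})

test_that("axon builder produces the documented particle counts", {
  counts <- function(b) as.vector(table(factor(b$system$kind, levels = 0:2)))
  b2 <- build_axon(model_config(n_rings = 2))
  expect_equal(counts(b2), c(78, 1599, 39))
  expect_equal(nrow(b2$system$pos), 1716)
  b3 <- build_axon(model_config(n_rings = 3))
  expect_equal(counts(b3), c(117, 3198, 78))
  # general formula: rings*39 actin, gaps*39*41 spectrin, gaps*39 ankyrin
  b5 <- build_axon(model_config(n_rings = 5, filaments_per_gap = 7))
  expect_equal(counts(b5), c(5 * 39, 4 * 7 * 41, 4 * 7))
})

test_that("axon topology has the right per-filament and per-ring structure", {
  b <- build_axon(model_config(n_rings = 2, filaments_per_gap = 1))
  t <- b$topology
  expect_equal(nrow(t$ss_bonds), 40)   # 41 beads: 40 bonds
  expect_equal(nrow(t$sk_bonds), 1)
  expect_equal(nrow(t$as_pairs), 2)
  expect_true(all(t$as_state == 1L))
  expect_equal(nrow(t$aa_bonds), 2 * 39)
  expect_equal(nrow(t$angles), 2 * 39)
  b3 <- build_axon(model_config(n_rings = 3))
  expect_equal(nrow(b3$topology$ss_bonds), 2 * 39 * 40)
  expect_equal(nrow(b3$topology$as_pairs), 2 * 39 * 2)
  expect_equal(nrow(b3$topology$sk_bonds), 2 * 39)
})

test_that("built geometry is planar rings at the configured spacing", {
  cfg <- model_config(n_rings = 3)
  b <- build_axon(cfg)
  us <- cfg$us
  z <- b$system$pos[, 3] * us$sigma_nm
  for (g in 1:3) {
    zg <- z[b$topology$ring_id == g]
    expect_equal(max(zg) - min(zg), 0)       # one z-plane per ring
    expect_equal(mean(zg), (g - 1) * 185)
  }
  rr <- sqrt(rowSums(b$system$pos[, 1:2]^2)) * us$sigma_nm
  expect_equal(unname(rr[b$system$kind == 0L][1]), cfg$ring_radius_nm,
               tolerance = 1e-10)
  # ankyrin sits at its confinement radius
  expect_equal(mean(rr[b$system$kind == 2L]), 232, tolerance = 1e-6)
})

test_that("junction offset gives the documented spectrin span", {
  cfg <- model_config(n_rings = 2)  # junction 20 nm
  b <- build_axon(cfg)
  sp <- which(b$system$kind == 1L)
  z <- b$system$pos[sp, 3] * cfg$us$sigma_nm
  # end-to-end span between first and last bead of any filament
  expect_equal(max(z) - min(z), 185 - 2 * 20)
  expect_gte(185 - 2 * 20, 145)
})

test_that("builders are deterministic", {
  b1 <- build_axon(model_config(n_rings = 3))
  b2 <- build_axon(model_config(n_rings = 3))
  expect_identical(b1$system$pos, b2$system$pos)
  expect_identical(b1$topology, b2$topology)
})

test_that("free spectrin chain is bonds-only at the contour length", {
  cfg <- model_config()
  b <- build_free_spectrin(cfg)
  expect_equal(nrow(b$system$pos), 41)
  expect_equal(nrow(b$topology$ss_bonds), 40)
  expect_equal(nrow(b$topology$angles), 0)
  expect_equal(nrow(b$topology$as_pairs), 0)
  expect_false(b$topology$confine)
  z <- b$system$pos[, 3] * cfg$us$sigma_nm
  expect_equal(max(z) - min(z), 40 * 5)  # Lc = 200 nm
  # two-bead degenerate chain: one bond at 5 nm
  b2 <- build_free_spectrin(model_config(beads_per_filament = 2,
                                         ankyrin_attach_index = 1))
  expect_equal(nrow(b2$topology$ss_bonds), 1)
  d <- sqrt(sum((b2$system$pos[2, ] - b2$system$pos[1, ])^2))
  expect_equal(d * cfg$us$sigma_nm, 5)
})

test_that("free ring filament has straight-angle FENE topology", {
  b <- build_free_ring_filament(3)
  expect_equal(nrow(b$topology$aa_bonds), 2)
  expect_equal(nrow(b$topology$angles), 1)
  expect_equal(b$topology$theta0, pi)
  b13 <- build_free_ring_filament(13)
  z <- b13$system$pos[, 3] * axon_units()$sigma_nm
  expect_equal(max(z) - min(z), 12 * 35)  # 420 nm contour
  bc <- build_free_ring_filament(5, clamped = TRUE)
  expect_identical(bc$system$clamped, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(build_free_ring_filament(2), "n_beads >= 3")
  expect_error(build_axon(model_config(n_rings = 1)), "n_rings >= 2")
})
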