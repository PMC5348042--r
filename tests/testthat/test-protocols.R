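test_that("free-chain statistics agree with the Monte Carlo oracle", {
  # Independent Metropolis MC (pivot + displacement) of the identical
  # Hamiltonian gives RMS ree = 53.2 +/- 0.2 nm at kT/eps = 0.03; the
  # ideal-chain limit (sterics off) is sqrt(40 * (a^2 + 3 kT/k0)) = 31.9 nm.
  fs <- free_filament_stats(model_config(seed = 3),
                            equil_steps = 1e5, production_steps = 2e6,
                            seed = 3)
  expect_equal(fs$rms_ree_nm, 53.2, tolerance = 0.06)
  expect_equal(fs$contour_nm, 200)
  expect_equal(fs$lp_nm, fs$rms_ree_nm^2 / 400)
  expect_gt(fs$sd_nm, 0)
})

test_that("free-chain statistics refuse an undersampled run", {
  expect_error(
    free_filament_stats(model_config(), equil_steps = 1000,
                        production_steps = 5000, sample_stride = 500),
    "too few")
})

test_that("cantilever tip variance matches the discrete-chain oracle", {
  cfg <- model_config(seed = 4)
  n <- 8
  br <- bending_rigidity(n_beads = n, cfg = cfg,
                         production_steps = 1.6e6, sample_stride = 400,
                         seed = 4)
  # independent joints: <u^2> per direction = kT/ktheta * a^2 * sum (n-j)^2
  ktheta <- (cfg$kb_kBT * 0.03) / (cfg$dtheta_max_frac * pi)
  a <- cfg$actin_bead_diameter_nm / cfg$us$sigma_nm
  du2_pred <- 0.03 / ktheta * a^2 * sum(seq_len(n - 2)^2)
  expect_equal(br$du2_mean, du2_pred, tolerance = 0.10)
  expect_equal(br$L_nm, (n - 2) * 35)
  # rigidity positive and on the ktheta*a scale set by the FENE stiffness
  expect_gt(br$kappa_Nm2, 0)
  kappa_scale <- ktheta * a * cfg$us$epsilon_J * cfg$us$sigma_m
  expect_equal(br$kappa_Nm2, kappa_scale, tolerance = 0.35)
})

test_that("stiffer bending restraints shrink cantilever fluctuations", {
  soft <- bending_rigidity(n_beads = 6, cfg = model_config(seed = 5),
                           production_steps = 2e5, seed = 5)
  stiff <- bending_rigidity(n_beads = 6,
                            cfg = model_config(kb_kBT = 35000, seed = 5),
                            production_steps = 2e5, seed = 5)
  expect_lt(stiff$du2_mean, soft$du2_mean / 3)
  expect_gt(stiff$kappa_Nm2, soft$kappa_Nm2 * 3)
})

test_that("radial expansion returns coherent stripe pressures and fits", {
  eq <- cached("exp2ring", {
    equilibrate(make_preset("axon_2ring", seed = 6), n_steps = 5e4,
                seed = 6)
  })
  st <- radial_expansion(eq, increments = 5, transition = 200,
                         equil_steps = 200, measure = 600,
                         ramp_in = 8000, seed = 7)
  expect_s3_class(st, "axskel_stiffness")
  expect_equal(nrow(st$increments), 5)
  expect_true(all(is.finite(c(st$E_ring_kPa, st$E_between_kPa,
                              st$E_avg_kPa))))
  expect_true(all(st$increments$p_ring >= 0))
  expect_true(all(st$increments$p_all >= 0))
  # the union pressure is exactly the area-weighted stripe combination
  inc <- st$increments
  n_r <- eq$topology$n_rings
  w_r <- 2 * pi * inc$r_c * (st$w_ring_nm / 4.45) * n_r
  w_b <- 2 * pi * inc$r_c * (st$w_between_nm / 4.45) * (n_r - 1)
  expect_equal(inc$p_all * (w_r + w_b),
               inc$p_ring * w_r + inc$p_between * w_b,
               tolerance = 1e-10)
  # ring-stripe pressure grows as the wall expands into the rings
  expect_gt(stats::cor(inc$r_c, inc$p_ring), 0.9)
})

test_that("ankyrin statistics are well-formed and spaced like the rings", {
  eq <- cached("ank2ring", {
    equilibrate(make_preset("axon_2ring", seed = 8), n_steps = 8e4,
                seed = 8)
  })
  a <- ankyrin_motion(eq, production_steps = 1e5, stride = 2e3, seed = 9)
  expect_s3_class(a, "axskel_ankyrin")
  expect_gt(a$radius_nm, 0)
  expect_length(a$radii_nm, 39)
  # single-gap model: Lc falls back to the configured ring spacing
  expect_equal(a$Lc_nm, 185, tolerance = 0.1)
  expect_gte(a$s, 0)
  expect_error(ankyrin_motion(eq, production_steps = 1e4, stride = 2e3),
               "10 sampling strides")
})

test_that("laceration bookkeeping: vacuous severing and monotone recovery", {
  eq <- cached("ank2ring", {
    equilibrate(make_preset("axon_2ring", seed = 8), n_steps = 8e4,
                seed = 8)
  })
  lac0 <- lacerate_and_watch(eq, n_severed = 0, evolve_steps = 500,
                             watch_steps = 1000, seed = 10)
  expect_true(all(lac0$series$fraction == 1))
  lac <- lacerate_and_watch(eq, n_severed = 10, evolve_steps = 2000,
                            watch_steps = 5000, log_stride = 250,
                            seed = 11)
  expect_length(lac$severed_pairs, 10)
  expect_true(all(diff(lac$series$n_reconnected) >= 0))
  expect_true(all(lac$series$fraction >= 0 & lac$series$fraction <= 1))
})

test_that("reconnection decreases with ring spacing and needs slack chains", {
  # a severed chain recoils to its thermal coil size (~53 nm end-to-end
  # here), so its free end can only re-find the vacated junction when the
  # junction-to-junction span is comparable to the coil; reconnection
  # fraction must fall off as the rings move apart
  frac_at <- function(spacing) {
    cfg <- model_config(n_rings = 3, ring_spacing_nm = spacing, seed = 12,
                        junction_override = TRUE)
    eq <- equilibrate(build_axon(cfg), n_steps = 8e4, seed = 12)
    lac <- lacerate_and_watch(eq, n_severed = 10, evolve_steps = 5e3,
                              watch_steps = 2e4, seed = 13)
    lac$fraction_final
  }
  f70 <- frac_at(70)
  f110 <- frac_at(110)
  f185 <- frac_at(185)
  expect_equal(f185, 0)   # taut chains cannot reach back
  expect_gte(f110, f185)
  expect_gte(f70, f110)
  expect_gt(f70, 0.3)     # slack chains re-associate readily
})
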