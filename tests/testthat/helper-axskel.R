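# Shared fixtures: equilibrated systems are expensive, so they are built
# lazily once per test run and cached.

.axskel_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .axskel_cache)) assign(key, force(expr), .axskel_cache)
  get(key, .axskel_cache)
}

equilibrated_axon <- function(spacing = 185, seed = 2, n_rings = 3,
                              n_steps = 1.5e5) {
  key <- sprintf("axon_%d_%d_%d", n_rings, spacing, seed)
  cached(key, {
    cfg <- model_config(n_rings = n_rings, ring_spacing_nm = spacing,
                        seed = seed)
    equilibrate(build_axon(cfg), n_steps = n_steps, seed = seed)
  })
}

# Central-difference gradient of the total potential energy
fd_forces <- function(system, topology, idx, h = 1e-5, wall_rc = NULL,
                      conf_track = FALSE) {
  out <- matrix(NA_real_, length(idx), 3)
  for (q in seq_along(idx)) {
    for (d in 1:3) {
      p1 <- system; p1$pos[idx[q], d] <- p1$pos[idx[q], d] + h
      p2 <- system; p2$pos[idx[q], d] <- p2$pos[idx[q], d] - h
      e1 <- total_forces(p1, topology, wall_rc, conf_track)$energy
      e2 <- total_forces(p2, topology, wall_rc, conf_track)$energy
      out[q, d] <- -(e1 - e2) / (2 * h)
    }
  }
  out
}
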