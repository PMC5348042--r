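#' Seeded preset systems
#'
#' Ready-to-run model builds with the published defaults frozen in, so
#' tests and analyses reference presets rather than ad-hoc configurations:
#' \describe{
#'   \item{free_spectrin}{41-bead free spectrin tetramer.}
#'   \item{free_actin_13}{13-bead straight actin-material filament
#'     (420 nm contour).}
#'   \item{axon_2ring}{2 rings, 1 gap: 78 + 1599 + 39 = 1716 particles.}
#'   \item{axon_3ring}{3 rings at 185 nm spacing (under tension):
#'     117 + 3198 + 78 = 3393 particles.}
#'   \item{axon_3ring_110nm}{3 rings at 110 nm spacing (spectrin near its
#'     thermal-equilibrium end-to-end distance).}
#'   \item{axon_full_11ring}{11 rings (~1.85 um of axon).}
#' }
#'
#' @param name Preset name.
#' @param seed RNG seed stored in the configuration.
#' @return List with `config`, `system`, `topology`.
#' @export
make_preset <- function(name = c("free_spectrin", "free_actin_13",
                                 "axon_2ring", "axon_3ring",
                                 "axon_3ring_110nm", "axon_full_11ring"),
                        seed = 1L) {
  name <- match.arg(name)
  switch(name,
    free_spectrin = {
      cfg <- model_config(seed = seed)
      c(list(config = cfg), build_free_spectrin(cfg))
    },
    free_actin_13 = {
      cfg <- model_config(seed = seed)
      c(list(config = cfg), build_free_ring_filament(13, cfg = cfg))
    },
    axon_2ring = {
      cfg <- model_config(n_rings = 2, seed = seed)
      c(list(config = cfg), build_axon(cfg))
    },
    axon_3ring = {
      cfg <- model_config(n_rings = 3, seed = seed)
      c(list(config = cfg), build_axon(cfg))
    },
    axon_3ring_110nm = {
      cfg <- model_config(n_rings = 3, ring_spacing_nm = 110, seed = seed)
      c(list(config = cfg), build_axon(cfg))
    },
    axon_full_11ring = {
      cfg <- model_config(n_rings = 11, seed = seed)
      c(list(config = cfg), build_axon(cfg))
    }
  )
}

#' Synthetic AFM indentation dataset
#'
#' Generates force-indentation curves from the closed-form power law of
#' the chosen geometry at a known modulus, with multiplicative Gaussian
#' noise on the force, emulating an indentation grid over a membrane
#' patch. Ground truth is stored for recovery tests.
#'
#' @param E_true True Young's modulus, kPa.
#' @param n_curves Number of curves (e.g. 256 for a 16 x 16 grid).
#' @param noise_frac Multiplicative noise standard deviation (0 = exact).
#' @param geometry `"thin_cylinder"` or `"cuboid"`.
#' @param d_max_nm Maximum indentation depth.
#' @param n_points Points per curve (uniform in depth).
#' @param seed RNG seed.
#' @return List with `curves` (list of data frames with `d_nm`, `F_pN`),
#'   `E_true`, `geometry`.
#' @export
make_afm_dataset <- function(E_true, n_curves = 256, noise_frac = 0.1,
                             geometry = c("thin_cylinder", "cuboid"),
                             d_max_nm = 100, n_points = 50, seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(E_true > 0, n_curves >= 0)
  d <- seq(0, d_max_nm, length.out = n_points + 1)[-1]
  F0 <- predict_force(E_true, d, geometry)
  curves <- if (n_curves == 0) list() else
    withr_seed(seed, lapply(seq_len(n_curves), function(i) {
      data.frame(d_nm = d,
                 F_pN = F0 * (1 + noise_frac * stats::rnorm(length(d))))
    }))
  list(curves = curves, E_true = E_true, geometry = geometry)
}

# evaluate `expr` under a local RNG seed without disturbing the caller's
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
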