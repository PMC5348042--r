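#' Closed-form AFM force-indentation laws
#'
#' Finite-element-derived power laws relating indentation depth to force
#' for the two probe-target geometries used on neurons: a thin-walled
#' cylinder (axon/dendrite), `F = 4.41e-3 * E * d^1.37`, and a
#' rectangular cuboid (soma-like slab), `F = 7.95e-3 * E * d^1.46`,
#' with `d` in nm, `E` in kPa and `F` in pN.
#'
#' @param E_kPa Young's modulus, kPa (>= 0).
#' @param d_nm Indentation depth(s), nm (>= 0).
#' @param geometry `"thin_cylinder"` or `"cuboid"`.
#' @return Force(s) in pN.
#' @examples
#' predict_force(4.6, 100, "thin_cylinder")  # ~11.1 pN
#' @export
predict_force <- function(E_kPa, d_nm,
                          geometry = c("thin_cylinder", "cuboid")) {
  geometry <- match.arg(geometry)
  stopifnot(all(E_kPa >= 0), all(d_nm >= 0))
  p <- afm_power_law(geometry)
  p$A * E_kPa * d_nm^p$alpha
}

afm_power_law <- function(geometry) {
  switch(geometry,
    thin_cylinder = list(A = 4.41e-3, alpha = 1.37),
    cuboid = list(A = 7.95e-3, alpha = 1.46),
    stop("unknown geometry tag: ", geometry)
  )
}

#' Fit a Young's modulus to an AFM force-indentation curve
#'
#' Least-squares fit of the geometry's fixed-exponent power law
#' `F = A(E) d^alpha` to a measured curve; the modulus is the only free
#' parameter (the prefactor is linear in E), so the estimate is the
#' closed-form linear least-squares solution on the fitting window.
#'
#' @param curve Data frame with columns `d_nm` (non-decreasing) and
#'   `F_pN`; the contact point is assumed already subtracted.
#' @param geometry `"thin_cylinder"` or `"cuboid"`.
#' @param d_window Indentation window (nm) used for the fit; only the
#'   shallow ~100 nm of an indentation is informative for the modulus.
#' @return List with `E_kPa`, `residual` (RMS force residual, pN), and
#'   `n_points` used.
#' @export
fit_modulus <- function(curve, geometry = c("thin_cylinder", "cuboid"),
                        d_window = c(0, 100)) {
  geometry <- match.arg(geometry)
  stopifnot(is.data.frame(curve), all(c("d_nm", "F_pN") %in% names(curve)))
  if (is.unsorted(curve$d_nm))
    stop("indentation depths must be non-decreasing")
  sel <- curve$d_nm >= d_window[1] & curve$d_nm <= d_window[2]
  d <- curve$d_nm[sel]; F <- curve$F_pN[sel]
  if (length(d) < 10)
    stop("need at least 10 points inside the fitting window")
  if (all(F == 0)) stop("all-zero force curve cannot be fitted")
  p <- afm_power_law(geometry)
  x <- p$A * d^p$alpha
  E <- sum(x * F) / sum(x * x)
  list(E_kPa = E, residual = sqrt(mean((F - E * x)^2)), n_points = length(d))
}

#' Summarize a grid of fitted moduli
#'
#' Pools per-curve modulus fits from an indentation grid (e.g. 16 x 16
#' points over a membrane patch) into a percentage histogram and reports
#' the median with a robust spread (median absolute deviation), the way
#' grid measurements are reduced to a single stiffness per cell region.
#'
#' @param E_kPa Numeric vector of fitted moduli.
#' @param breaks Histogram breaks (passed to [hist()]).
#' @return List with `median_kPa`, `mad_kPa`, `histogram` (data frame of
#'   bin midpoints and percentage frequency), and `n`.
#' @export
summarize_grid <- function(E_kPa, breaks = "Sturges") {
  stopifnot(length(E_kPa) >= 1)
  h <- graphics::hist(E_kPa, breaks = breaks, plot = FALSE)
  list(median_kPa = stats::median(E_kPa),
       mad_kPa = stats::mad(E_kPa),
       histogram = data.frame(mid_kPa = h$mids,
                              percent = 100 * h$counts / length(E_kPa)),
       n = length(E_kPa))
}

#' Read an AFM force curve from a delimited text file
#'
#' Two-column delimited text with a header naming the columns `d_nm` and
#' `F_pN` (indentation in nm, force in pN).
#'
#' @param path File path.
#' @param sep Field separator (whitespace by default).
#' @return Data frame with `d_nm` and `F_pN`.
#' @export
read_force_curve <- function(path, sep = "") {
  x <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("d_nm", "F_pN") %in% names(x)))
    stop("force-curve file must have columns 'd_nm' and 'F_pN'")
  x[, c("d_nm", "F_pN")]
}
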