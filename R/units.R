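#' Reduced unit system for the axon membrane-skeleton model
#'
#' The model is formulated in reduced Lennard-Jones style units: a length
#' unit `sigma`, an energy unit `eps`, and a mass unit `m` (the mass of one
#' spectrin bead, set to 1). The length unit is fixed by requiring that the
#' equilibrium spacing of the spectrin-spectrin repulsion,
#' `2^(1/6) * sigma`, equals the 5 nm spectrin bead spacing, giving
#' `sigma = 4.45 nm`. The energy unit is fixed by running the model at
#' reduced temperature `kB*T/eps = 0.03` with `T = 300 K`, giving
#' `eps = kB*300/0.03 ~ 0.86 eV`. The time unit is
#' `t_s = sqrt(m * sigma^2 / eps)`.
#'
#' The bead mass is never assigned an SI value by the model (equilibrium
#' statistics are mass independent), so conversion of *times* to seconds is
#' only possible when `mass_kg` is supplied explicitly.
#'
#' @param sigma_nm Length unit in nanometres.
#' @param T_kelvin Absolute temperature in kelvin.
#' @param kT_over_eps Reduced temperature; together with `T_kelvin` this
#'   fixes the energy unit `eps = kB*T_kelvin/kT_over_eps`.
#' @param mass_kg Optional SI mass of one bead (kg); only needed to convert
#'   reduced times to seconds.
#' @return An object of class `axskel_units` with fields `sigma_nm`,
#'   `sigma_m`, `epsilon_J`, `kT_over_eps`, `T_kelvin`, `kB`, `mass_kg`.
#' @examples
#' us <- axon_units()
#' to_SI(38.0, "stiffness", us)      # 0.26 N/m actin spring constant
#' to_SI(7.22e-4, "pressure", us)    # ~1130 Pa = 1.13 kPa
#' @export
axon_units <- function(sigma_nm = 4.45, T_kelvin = 300, kT_over_eps = 0.03,
                       mass_kg = NA_real_) {
  stopifnot(sigma_nm > 0, T_kelvin > 0, kT_over_eps > 0)
  kB <- 1.380649e-23
  us <- list(
    sigma_nm    = sigma_nm,
    sigma_m     = sigma_nm * 1e-9,
    epsilon_J   = kB * T_kelvin / kT_over_eps,
    kT_over_eps = kT_over_eps,
    T_kelvin    = T_kelvin,
    kB          = kB,
    mass_kg     = mass_kg
  )
  class(us) <- "axskel_units"
  us
}

#' @export
print.axskel_units <- function(x, ...) {
  ev <- x$epsilon_J / 1.602176634e-19
  cat("axskel reduced units:\n")
  cat(sprintf("  sigma = %.4g nm   eps = %.4g J (%.4g eV)\n",
              x$sigma_nm, x$epsilon_J, ev))
  cat(sprintf("  kB*T/eps = %.4g at T = %g K\n", x$kT_over_eps, x$T_kelvin))
  cat(sprintf("  eps/sigma^3 = %.4g Pa, eps/sigma^2 = %.4g N/m\n",
              x$epsilon_J / x$sigma_m^3, x$epsilon_J / x$sigma_m^2))
  invisible(x)
}

.si_factor <- function(quantity_kind, us) {
  switch(quantity_kind,
    length    = us$sigma_m,
    energy    = us$epsilon_J,
    force     = us$epsilon_J / us$sigma_m,
    stiffness = us$epsilon_J / us$sigma_m^2,
    pressure  = us$epsilon_J / us$sigma_m^3,
    time      = {
      if (is.na(us$mass_kg))
        stop("converting time requires an SI bead mass: set `mass_kg` in axon_units()")
      sqrt(us$mass_kg * us$sigma_m^2 / us$epsilon_J)
    },
    stop("unknown quantity_kind: ", quantity_kind)
  )
}

#' Convert between reduced and SI units
#'
#' `to_SI()` converts a value in reduced units (`sigma`, `eps`, `t_s`) to SI
#' base units (m, J, N, N/m, Pa, s); `from_SI()` is the exact inverse.
#'
#' @param value Numeric vector in reduced (resp. SI) units.
#' @param quantity_kind One of `"length"`, `"energy"`, `"force"`,
#'   `"stiffness"` (N/m), `"pressure"` (Pa), `"time"`.
#' @param us A unit system from [axon_units()].
#' @return Numeric vector in SI (resp. reduced) units.
#' @export
to_SI <- function(value, quantity_kind, us = axon_units()) {
  value * .si_factor(quantity_kind, us)
}

#' @rdname to_SI
#' @export
from_SI <- function(value, quantity_kind, us = axon_units()) {
  value / .si_factor(quantity_kind, us)
}

#' Convert a length in nanometres to reduced units
#' @param nm length(s) in nm
#' @param us unit system
#' @return length(s) in sigma
#' @keywords internal
nm_to_red <- function(nm, us = axon_units()) nm / us$sigma_nm

#' @rdname nm_to_red
#' @param red length(s) in sigma
#' @keywords internal
red_to_nm <- function(red, us = axon_units()) red * us$sigma_nm
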