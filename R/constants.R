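#' Physical constants (CODATA 2018)
#'
#' Returns the fixed set of physical constants used throughout the package.
#' All internal computation is carried out in eV and seconds; unit conversion
#' happens only at input/output boundaries.
#'
#' @return A named list with components:
#' \describe{
#'   \item{k_B}{Boltzmann constant, eV/K.}
#'   \item{h}{Planck constant, eV s.}
#'   \item{hbar}{Reduced Planck constant \eqn{h/2\pi}, eV s.}
#'   \item{hartree_to_eV}{1 hartree in eV.}
#'   \item{eV_to_kcal_per_mol}{1 eV in kcal/mol.}
#'   \item{hc}{Photon-energy constant \eqn{hc}, eV nm.}
#'   \item{eV_to_joule}{1 eV in J.}
#'   \item{amu_to_kg}{1 unified atomic mass unit in kg.}
#'   \item{avogadro}{Avogadro constant, 1/mol.}
#' }
#' @examples
#' physical_constants()$k_B
#' @export
physical_constants <- function() {
  # k_B, h and c are exact in the SI since the 2019 redefinition; the
  # eV-scale values (8.617333262e-5 eV/K, 4.135667696e-15 eV s,
  # hc = 1239.841984 eV nm) are derived here from the exact SI constants so
  # that eV-unit and SI-unit evaluations of the same expression agree to
  # machine precision
  e_C <- 1.602176634e-19      # elementary charge, C (exact)
  h_J <- 6.62607015e-34       # Planck constant, J s (exact)
  c_ms <- 299792458           # speed of light, m/s (exact)
  list(
    k_B              = 1.380649e-23 / e_C,   # eV/K
    h                = h_J / e_C,            # eV s
    hbar             = h_J / e_C / (2 * pi),
    hartree_to_eV    = 27.211386245988,
    eV_to_kcal_per_mol = 23.060548,
    hc               = h_J * c_ms / e_C * 1e9,  # eV nm
    eV_to_joule      = e_C,
    amu_to_kg        = 1.66053906660e-27,
    avogadro         = 6.02214076e23
  )
}

# internal shorthand; a plain list so hot paths avoid repeated construction
.const <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- physical_constants()
    cache
  }
})

#' Supported energy units
#'
#' @return Character vector of the unit tags accepted by [convert_energy()].
#' @export
energy_units <- function() {
  c("hartree", "eV", "kcal_per_mol", "cm_inverse", "joule")
}

# conversion factors to eV, the internal working unit
.to_eV_factor <- function(unit) {
  cst <- .const()
  switch(unit,
    hartree      = cst$hartree_to_eV,
    eV           = 1,
    kcal_per_mol = 1 / cst$eV_to_kcal_per_mol,
    cm_inverse   = cst$hc * 1e-7,   # hc in eV cm: 1239.841984 eV nm * 1e-7 cm/nm
    joule        = 1 / cst$eV_to_joule,
    stop("unknown energy unit '", unit, "'; expected one of: ",
         paste(energy_units(), collapse = ", "), call. = FALSE)
  )
}

#' Convert energies between units
#'
#' Linear conversion between the five energy units used in quantum-chemical
#' thermochemistry, with factors pinned to CODATA 2018. Vectorised over
#' `x`.
#'
#' @param x Numeric vector of energy magnitudes.
#' @param from,to Unit tags; see [energy_units()].
#' @return Numeric vector of the same length as `x`, in units `to`.
#' @examples
#' convert_energy(0.126277, "hartree", "eV")       # ~3.436
#' convert_energy(1, "eV", "kcal_per_mol")         # 23.0605
#' @export
convert_energy <- function(x, from, to) {
  stopifnot(is.numeric(x))
  x * (.to_eV_factor(from) / .to_eV_factor(to))
}

#' Photon energy of a wavelength
#'
#' Computes \eqn{E = hc/\lambda} in eV for a wavelength in nm.
#'
#' Note that a UVA band edge of 321 nm corresponds to 3.862 eV and 308 nm to
#' 4.025 eV with the CODATA value of \eqn{hc}; some literature tabulations
#' quote 3.89 and 4.05 eV for these wavelengths. This function always returns
#' the computed \eqn{hc/\lambda}; band edges used for feasibility gating are a
#' user-supplied configuration value (see [radiation_band()]).
#'
#' @param wavelength_nm Positive numeric vector of wavelengths in nm.
#' @return Photon energies in eV.
#' @examples
#' wavelength_to_photon_energy(321)
#' @export
wavelength_to_photon_energy <- function(wavelength_nm) {
  stopifnot(is.numeric(wavelength_nm))
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0)) {
    stop("wavelength must be finite and positive (nm)", call. = FALSE)
  }
  .const()$hc / wavelength_nm
}
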