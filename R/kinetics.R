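# Nonadiabatic kinetics: canonical TST with photon-energy partitioning,
# semiclassical Marcus ISC rates, Landau-Zener hopping, and the
# excitation-decay cycle conversion model. All energies in eV, times in s,
# temperatures in K; exponents above .rate_overflow_exponent in natural-log
# space return a flagged +Inf rather than wrapping silently.

.rate_overflow_exponent <- 700

#' Rate / probability result
#'
#' Light container for a computed rate constant or probability, carrying the
#' Boltzmann/Gaussian exponent actually used so extreme results can be
#' audited.
#'
#' @param value Numeric value.
#' @param unit One of `"per_molar_per_second"`, `"per_second"`,
#'   `"probability"`, `"dimensionless"`.
#' @param exponent_diagnostic The exponent entering the dominant exponential
#'   factor (natural log scale), or `NA` when none applies.
#' @param overflow Logical; `TRUE` when the exponential overflowed and the
#'   value is a flagged `Inf`.
#' @return An object of class `rate_result`.
#' @export
rate_result <- function(value, unit, exponent_diagnostic = NA_real_,
                        overflow = FALSE) {
  unit <- match.arg(unit, c("per_molar_per_second", "per_second",
                            "probability", "dimensionless"))
  if (unit == "probability" && is.finite(value) &&
      (value < 0 || value > 1)) {
    stop("probability result outside [0, 1]", call. = FALSE)
  }
  if (is.finite(value) && value < 0) {
    stop("rate results must be non-negative", call. = FALSE)
  }
  structure(list(value = value, unit = unit,
                 exponent_diagnostic = exponent_diagnostic,
                 overflow = isTRUE(overflow)),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  lab <- switch(x$unit,
                per_molar_per_second = "M^-1 s^-1",
                per_second = "s^-1",
                probability = "(probability)",
                dimensionless = "(dimensionless)")
  cat(sprintf("%.4g %s%s", x$value, lab,
              if (x$overflow) "  [exponential overflow]" else ""), "\n")
  if (is.finite(x$exponent_diagnostic)) {
    cat(sprintf("  exponent: %.6g\n", x$exponent_diagnostic))
  }
  invisible(x)
}

.exp_guarded <- function(expo) {
  if (expo > .rate_overflow_exponent) {
    list(value = Inf, overflow = TRUE)
  } else {
    list(value = exp(expo), overflow = FALSE)
  }
}

#' Rigid-rotor harmonic-oscillator partition functions
#'
#' Computes the translational, rotational and vibrational partition-function
#' factors of a species in the RRHO approximation. The translational factor
#' is evaluated per standard-state volume (default 1 mol/L), so ratios of
#' these q values feed directly into a bimolecular rate in M^-1 s^-1. The
#' vibrational factor uses the ZPE-referenced convention
#' \eqn{q_v = \prod_i (1 - e^{-h\nu_i/k_BT})^{-1}} (the energy zero is
#' handled separately through the ZPE-corrected energies of the rate
#' expression).
#'
#' @param mass_amu Total mass, unified atomic mass units.
#' @param frequencies_cm Harmonic frequencies, cm^-1; must all be positive
#'   (drop the imaginary reaction mode of a transition state before calling).
#'   Use `numeric(0)` for an atom.
#' @param rotational_constants_cm Rotational constants, cm^-1: length 0 for
#'   an atom, 1 for a linear rotor, 3 for a nonlinear top.
#' @param temperature Temperature, K.
#' @param symmetry_number Rotational symmetry number (default 1).
#' @param standard_concentration Standard state, mol/L (default 1).
#' @return A list with components `q_trans`, `q_rot`, `q_vib` and their
#'   product `q_total`.
#' @examples
#' # hydrogen atom at 298.15 K, 1 M standard state
#' rrho_partition_functions(1.008, numeric(0), numeric(0), 298.15)
#' @export
rrho_partition_functions <- function(mass_amu, frequencies_cm,
                                     rotational_constants_cm,
                                     temperature,
                                     symmetry_number = 1,
                                     standard_concentration = 1) {
  stopifnot(is.numeric(mass_amu), mass_amu > 0,
            is.numeric(temperature), temperature > 0,
            standard_concentration > 0, symmetry_number >= 1)
  if (length(frequencies_cm) && any(frequencies_cm <= 0)) {
    stop("all frequencies must be positive; drop the imaginary reaction mode ",
         "of a transition state before computing its partition function",
         call. = FALSE)
  }
  cst <- .const()
  kT_J <- cst$k_B * temperature * cst$eV_to_joule
  h_J <- cst$h * cst$eV_to_joule
  m_kg <- mass_amu * cst$amu_to_kg
  # volume per molecule at the standard concentration, m^3
  vol <- 1 / (cst$avogadro * standard_concentration * 1000)
  q_trans <- (2 * pi * m_kg * kT_J / h_J^2)^1.5 * vol
  kT_cm <- cst$k_B * temperature / (cst$hc * 1e-7)  # k_B T in cm^-1
  nrot <- length(rotational_constants_cm)
  q_rot <- if (nrot == 0L) {
    1
  } else if (nrot == 1L) {
    kT_cm / (symmetry_number * rotational_constants_cm)
  } else if (nrot == 3L) {
    sqrt(pi) / symmetry_number *
      sqrt(kT_cm^3 / prod(rotational_constants_cm))
  } else {
    stop("rotational_constants_cm must have length 0 (atom), 1 (linear) or 3 ",
         "(nonlinear top)", call. = FALSE)
  }
  q_vib <- if (length(frequencies_cm)) {
    prod(1 / (1 - exp(-frequencies_cm / kT_cm)))
  } else 1
  list(q_trans = q_trans, q_rot = q_rot, q_vib = q_vib,
       q_total = q_trans * q_rot * q_vib)
}

#' Bimolecular TST rate with photon-energy partitioning
#'
#' Canonical transition-state rate for the recombination of a heavy radical
#' with a hydrogen atom, modified so that a fraction `x` of the absorbed
#' photon energy `e_p` is carried by the light fragment and lowers the
#' effective barrier:
#' \deqn{k = \frac{k_B T}{h}\,\frac{Q^{TS}}{Q_{frag} Q_{H}}
#'   \exp\!\left(-\frac{U^{TS}_0 - U^{frag}_0 - U^{H}_0 - x e_p}{k_B T}\right)}
#' The partition functions are taken per standard-state volume (see
#' [rrho_partition_functions()]), giving the rate in M^-1 s^-1. The fraction
#' of photon energy absorbed by the heavy fragment is assumed to spread over
#' its many internal modes and persist into the transition state, leaving
#' the rate unchanged — hence only `x * e_p` enters.
#'
#' @param q_ts,q_fragment,q_atom Total partition functions of the transition
#'   state, the heavy radical and the H atom (per standard-state volume).
#' @param u_ts_0,u_fragment_0,u_atom_0 ZPE-corrected energies, eV, on a
#'   common reference.
#' @param x Fraction of the photon energy given to the light fragment, in
#'   \[0, 1\].
#' @param e_p Photon energy, eV.
#' @param temperature Temperature, K (default 298.15).
#' @return A [rate_result()] in M^-1 s^-1 with `exponent_diagnostic` holding
#'   the full Boltzmann exponent.
#' @export
tst_rate <- function(q_ts, q_fragment, q_atom,
                     u_ts_0, u_fragment_0, u_atom_0,
                     x = 0, e_p = 0, temperature = 298.15) {
  stopifnot(q_ts > 0, q_fragment > 0, q_atom > 0,
            is.finite(u_ts_0), is.finite(u_fragment_0), is.finite(u_atom_0),
            x >= 0, x <= 1, e_p >= 0, temperature > 0)
  cst <- .const()
  kT <- cst$k_B * temperature
  expo <- -(u_ts_0 - u_fragment_0 - u_atom_0 - x * e_p) / kT
  ex <- .exp_guarded(expo)
  pref <- (kT / cst$h) * q_ts / (q_fragment * q_atom)
  rate_result(pref * ex$value, "per_molar_per_second",
              exponent_diagnostic = expo, overflow = ex$overflow)
}

#' Photon-boost series of rate constants
#'
#' Scales a baseline bimolecular rate constant `k0` (the rate at `x = 0`) by
#' the photon-partition factor \eqn{\exp(x e_p / k_B T)} over a set of
#' fractions, and appends the pseudo-first-order column for a fixed partner
#' concentration.
#'
#' @param k0 Baseline second-order rate constant, M^-1 s^-1.
#' @param e_p Photon energy, eV.
#' @param temperature Temperature, K (default 298.15).
#' @param fractions Numeric vector of photon-energy fractions x in \[0, 1\].
#' @param concentration Partner concentration, mol/L, for the
#'   pseudo-first-order column (default 0.005).
#' @return A data.frame with columns `x`, `k_second_order` (M^-1 s^-1) and
#'   `k_pseudo_first_order` (s^-1).
#' @examples
#' photon_boost_series(1.11e-3, e_p = 3.49,
#'                     fractions = c(0, 0.1, 0.2, 0.3, 0.35, 0.4))
#' @export
photon_boost_series <- function(k0, e_p, temperature = 298.15,
                                fractions = seq(0, 0.4, by = 0.1),
                                concentration = 0.005) {
  stopifnot(is.numeric(k0), k0 > 0, e_p >= 0, temperature > 0,
            all(fractions >= 0), all(fractions <= 1), concentration >= 0)
  kT <- .const()$k_B * temperature
  expo <- fractions * e_p / kT
  k2 <- ifelse(expo > .rate_overflow_exponent, Inf, k0 * exp(expo))
  data.frame(x = fractions,
             k_second_order = k2,
             k_pseudo_first_order = k2 * concentration)
}

#' Pseudo-first-order rate constant
#'
#' Converts a bimolecular rate constant to a pseudo-first-order one at a
#' fixed concentration of the partner species.
#'
#' @param k2 Second-order rate constant, M^-1 s^-1.
#' @param concentration Partner concentration, mol/L.
#' @return A [rate_result()] in s^-1.
#' @examples
#' pseudo_first_order(1.11e-3, 0.005)  # 5.55e-6 s^-1
#' @export
pseudo_first_order <- function(k2, concentration) {
  stopifnot(is.numeric(k2), k2 >= 0, is.numeric(concentration),
            concentration >= 0)
  rate_result(k2 * concentration, "per_second")
}

#' Semiclassical Marcus intersystem-crossing rate
#'
#' Golden-rule rate for the radiationless singlet-to-triplet transition at a
#' curve crossing, in the semiclassical Marcus form:
#' \deqn{k_{ISC} = \frac{V_{SOC}^2}{\hbar}
#'   \sqrt{\frac{\pi}{\lambda k_B T}}
#'   \exp\!\left(-\frac{(\Delta G^v_{ST} + \lambda)^2}{4 \lambda k_B T}\right)}
#' The rate is maximal (activationless) at \eqn{\Delta G^v_{ST} = -\lambda}
#' and quadratic in the spin-orbit coupling.
#'
#' @param v_soc Spin-orbit coupling matrix element; eV by default, cm^-1 if
#'   `coupling_unit = "cm_inverse"`.
#' @param lambda_reorg Reorganization energy, eV; must be positive.
#' @param delta_g_st Vertical free-energy gap between the singlet and
#'   triplet states, eV.
#' @param temperature Temperature, K (default 298.15).
#' @param coupling_unit Unit of `v_soc`: `"eV"` or `"cm_inverse"`.
#' @return A [rate_result()] in s^-1 with the Gaussian exponent recorded.
#' @examples
#' marcus_isc_rate(100, lambda_reorg = 0.5, delta_g_st = -0.2,
#'                 coupling_unit = "cm_inverse")
#' @export
marcus_isc_rate <- function(v_soc, lambda_reorg, delta_g_st,
                            temperature = 298.15,
                            coupling_unit = c("eV", "cm_inverse")) {
  coupling_unit <- match.arg(coupling_unit)
  stopifnot(is.numeric(v_soc), v_soc >= 0, is.finite(delta_g_st),
            temperature > 0)
  if (!is.numeric(lambda_reorg) || lambda_reorg <= 0) {
    stop("reorganization energy must be positive (eV)", call. = FALSE)
  }
  if (coupling_unit == "cm_inverse") {
    v_soc <- convert_energy(v_soc, "cm_inverse", "eV")
  }
  cst <- .const()
  kT <- cst$k_B * temperature
  expo <- -(delta_g_st + lambda_reorg)^2 / (4 * lambda_reorg * kT)
  k <- (v_soc^2 / cst$hbar) * sqrt(pi / (lambda_reorg * kT)) * exp(expo)
  rate_result(k, "per_second", exponent_diagnostic = expo)
}

#' Landau-Zener hopping probability
#'
#' Probability of hopping between two crossing diabatic curves of different
#' spin multiplicity on passage through the crossing region:
#' \deqn{P = 1 - \exp\!\left(-\frac{2\pi V^2}{\hbar\, v\, |\Delta F|}\right)}
#' with the coupling `V` (here the spin-orbit coupling at the crossing), the
#' nuclear velocity `v` through the crossing and the difference of the
#' diabatic slopes \eqn{|\Delta F|}. Single passage is the default; the
#' `"double"` variant accounts for a hop on either the outgoing or the
#' returning pass of one traversal cycle, \eqn{P(2 - P)}.
#'
#' @param coupling Coupling at the crossing; eV by default, cm^-1 if
#'   `coupling_unit = "cm_inverse"`.
#' @param velocity Nuclear velocity through the crossing, angstrom/s; must be
#'   positive.
#' @param slope_difference Absolute difference of the two curves' slopes at
#'   the crossing, eV/angstrom; must be positive.
#' @param passages `"single"` (default) or `"double"`.
#' @param coupling_unit Unit of `coupling`.
#' @return A [rate_result()] with `unit = "probability"`; the Landau-Zener
#'   exponent is recorded in `exponent_diagnostic`.
#' @examples
#' landau_zener_probability(50, velocity = 5e13, slope_difference = 2,
#'                          coupling_unit = "cm_inverse")
#' @export
landau_zener_probability <- function(coupling, velocity, slope_difference,
                                     passages = c("single", "double"),
                                     coupling_unit = c("eV", "cm_inverse")) {
  passages <- match.arg(passages)
  coupling_unit <- match.arg(coupling_unit)
  stopifnot(is.numeric(coupling), coupling >= 0)
  if (!is.numeric(velocity) || velocity <= 0 ||
      !is.numeric(slope_difference) || slope_difference <= 0) {
    stop("velocity and slope difference must be positive; the adiabatic ",
         "limit is undefined in this form", call. = FALSE)
  }
  if (coupling_unit == "cm_inverse") {
    coupling <- convert_energy(coupling, "cm_inverse", "eV")
  }
  expo <- 2 * pi * coupling^2 / (.const()$hbar * velocity * slope_difference)
  p <- 1 - exp(-expo)
  if (passages == "double") p <- p * (2 - p)
  rate_result(p, "probability", exponent_diagnostic = -expo)
}

#' Converted fraction after repeated excitation-decay cycles
#'
#' Population that has crossed to the triplet manifold after `cycles`
#' excitation-decay rounds when each cycle converts a fraction `p`:
#' \eqn{1 - (1 - p)^{n}}. Models a photochemical scheme in which the singlet
#' population returned by the radiationless decay channel can absorb again,
#' so the conversion approaches completion over many cycles.
#'
#' @param p_triplet_per_cycle Per-cycle conversion probability in \[0, 1\].
#' @param cycles Non-negative integer number of cycles.
#' @return The converted fraction in \[0, 1\].
#' @examples
#' cycle_conversion(0.5, 2)  # 0.75
#' @export
cycle_conversion <- function(p_triplet_per_cycle, cycles) {
  stopifnot(is.numeric(p_triplet_per_cycle),
            all(p_triplet_per_cycle >= 0), all(p_triplet_per_cycle <= 1),
            is.numeric(cycles), all(cycles >= 0),
            all(cycles == floor(cycles)))
  1 - (1 - p_triplet_per_cycle)^cycles
}
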