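#' Species-energy ledger
#'
#' A ledger collects one record per chemical species — tautomers, radical
#' asymptotes, transition states, triplet wells — each with a correlated
#' electronic energy and a harmonic zero-point energy (ZPE), both in hartree,
#' plus a spin multiplicity and a role tag. Relative energies are always
#' taken against a declared reference species (the zero of the scale),
#' conventionally the most stable tautomer.
#'
#' @param records A data.frame with columns `label`,
#'   `electronic_energy_hartree`, `zpe_hartree`, `multiplicity`, `role`.
#' @param reference Label of the reference species (must be present).
#' @return An object of class `species_ledger`.
#' @examples
#' led <- species_ledger(
#'   data.frame(
#'     label = c("A", "B"),
#'     electronic_energy_hartree = c(-100.10, -100.00),
#'     zpe_hartree = c(0.05, 0.04),
#'     multiplicity = c("singlet", "triplet"),
#'     role = c("tautomer", "radical_asymptote")
#'   ),
#'   reference = "A"
#' )
#' relative_energies(led)
#' @seealso [read_species_ledger()], [relative_energies()], [feasibility_gate()]
#' @export
species_ledger <- function(records, reference) {
  stopifnot(is.data.frame(records))
  needed <- c("label", "electronic_energy_hartree", "zpe_hartree",
              "multiplicity", "role")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("ledger is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records$label <- as.character(records$label)
  if (anyDuplicated(records$label)) {
    stop("duplicate species labels in ledger: ",
         paste(unique(records$label[duplicated(records$label)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.character(reference) || length(reference) != 1L ||
      !(reference %in% records$label)) {
    stop("reference label not found in ledger", call. = FALSE)
  }
  if (any(!is.finite(records$electronic_energy_hartree))) {
    stop("non-finite electronic energies in ledger", call. = FALSE)
  }
  if (any(!is.finite(records$zpe_hartree)) || any(records$zpe_hartree < 0)) {
    stop("ZPE must be finite and non-negative", call. = FALSE)
  }
  mult_ok <- records$multiplicity %in% c("singlet", "doublet_pair", "triplet")
  if (!all(mult_ok)) {
    stop("unknown multiplicity tag(s): ",
         paste(unique(records$multiplicity[!mult_ok]), collapse = ", "),
         call. = FALSE)
  }
  role_ok <- records$role %in%
    c("tautomer", "radical_asymptote", "transition_state", "triplet_well")
  if (!all(role_ok)) {
    stop("unknown role tag(s): ",
         paste(unique(records$role[!role_ok]), collapse = ", "), call. = FALSE)
  }
  structure(list(records = records, reference = reference),
            class = "species_ledger")
}

#' Read a species ledger from CSV
#'
#' Expected header:
#' `label,electronic_energy_hartree,zpe_hartree,multiplicity,role`.
#'
#' @param path Path to a CSV file.
#' @param reference Label of the reference species.
#' @return A [species_ledger()].
#' @export
read_species_ledger <- function(path, reference) {
  if (!file.exists(path)) stop("ledger file not found: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  species_ledger(records, reference)
}

#' @export
print.species_ledger <- function(x, ...) {
  cat("Species-energy ledger:", nrow(x$records), "records, reference",
      sQuote(x$reference), "\n")
  print(x$records, row.names = FALSE)
  invisible(x)
}

#' Relative-energy table
#'
#' Computes energies relative to the ledger's reference species, in eV and
#' kcal/mol, both derived from the same hartree difference. With
#' `use_zpe = TRUE` (the default) the ZPE-corrected energy
#' (electronic + ZPE) is differenced; otherwise the electronic energy alone.
#' Rows are sorted by increasing relative energy; the reference row is
#' exactly zero.
#'
#' Full double precision is retained in the returned columns; the print
#' method rounds to the conventional display precision (eV to 2 decimals,
#' kcal/mol to 1 decimal).
#'
#' @param ledger A [species_ledger()].
#' @param use_zpe Logical; include the ZPE correction in the difference.
#' @return A data.frame of class `relative_energy_table` with columns
#'   `label`, `multiplicity`, `role`, `rel_energy_hartree`, `rel_energy_eV`,
#'   `rel_energy_kcal`.
#' @export
relative_energies <- function(ledger, use_zpe = TRUE) {
  stopifnot(inherits(ledger, "species_ledger"))
  rec <- ledger$records
  e <- rec$electronic_energy_hartree
  if (isTRUE(use_zpe)) e <- e + rec$zpe_hartree
  d_ha <- e - e[match(ledger$reference, rec$label)]
  out <- data.frame(
    label = rec$label,
    multiplicity = rec$multiplicity,
    role = rec$role,
    rel_energy_hartree = d_ha,
    rel_energy_eV = convert_energy(d_ha, "hartree", "eV"),
    rel_energy_kcal = convert_energy(d_ha, "hartree", "kcal_per_mol"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rel_energy_eV), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference") <- ledger$reference
  attr(out, "use_zpe") <- isTRUE(use_zpe)
  class(out) <- c("relative_energy_table", "data.frame")
  out
}

#' @export
print.relative_energy_table <- function(x, ...) {
  cat("Relative energies (reference ", sQuote(attr(x, "reference")),
      if (isTRUE(attr(x, "use_zpe"))) ", ZPE-corrected" else ", electronic only",
      ")\n", sep = "")
  shown <- data.frame(
    label = x$label,
    multiplicity = x$multiplicity,
    role = x$role,
    eV = sprintf("%.2f", x$rel_energy_eV),
    kcal_mol = sprintf("%.1f", x$rel_energy_kcal),
    stringsAsFactors = FALSE
  )
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Radiation band
#'
#' A named photon-energy window used for feasibility gating, e.g. UVA with an
#' upper edge of 3.89 eV.
#'
#' @param name Band name (e.g. `"UVA"`).
#' @param max_photon_energy Upper photon energy of the band, eV.
#' @param min_photon_energy Lower photon energy, eV (default 0).
#' @return An object of class `radiation_band`.
#' @export
radiation_band <- function(name, max_photon_energy, min_photon_energy = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(max_photon_energy), length(max_photon_energy) == 1L,
            is.numeric(min_photon_energy), length(min_photon_energy) == 1L)
  if (!is.finite(max_photon_energy) || !is.finite(min_photon_energy) ||
      min_photon_energy < 0 || max_photon_energy < min_photon_energy) {
    stop("band edges must satisfy max >= min >= 0 (eV)", call. = FALSE)
  }
  structure(list(name = name, max_photon_energy = max_photon_energy,
                 min_photon_energy = min_photon_energy),
            class = "radiation_band")
}

#' @export
print.radiation_band <- function(x, ...) {
  cat(sprintf("Radiation band %s: [%.3f, %.3f] eV\n",
              x$name, x$min_photon_energy, x$max_photon_energy))
  invisible(x)
}

#' Photon-feasibility gate for a cleavage channel
#'
#' Decides whether a radical asymptote at the given relative energy is
#' energetically reachable by single-photon absorption within a radiation
#' band: reachable iff the asymptote energy does not exceed the band's upper
#' photon energy (inclusive boundary). The signed margin is
#' `max_photon_energy - asymptote`, positive when reachable with energy to
#' spare.
#'
#' @param asymptote_rel_energy Numeric vector of asymptote energies relative
#'   to the ground-state reference, eV.
#' @param band A [radiation_band()].
#' @return A data.frame with columns `asymptote_eV`, `band`, `verdict`
#'   (`"reachable"`/`"unreachable"`) and `margin_eV`.
#' @examples
#' feasibility_gate(c(3.43, 4.19), radiation_band("UVA", 3.89))
#' @export
feasibility_gate <- function(asymptote_rel_energy, band) {
  stopifnot(is.numeric(asymptote_rel_energy), inherits(band, "radiation_band"))
  if (any(!is.finite(asymptote_rel_energy))) {
    stop("asymptote energies must be finite", call. = FALSE)
  }
  if (any(asymptote_rel_energy < 0)) {
    warning("asymptote energy below the ground-state reference is physically suspect",
            call. = FALSE)
  }
  reach <- asymptote_rel_energy <= band$max_photon_energy
  data.frame(
    asymptote_eV = asymptote_rel_energy,
    band = band$name,
    verdict = ifelse(reach, "reachable", "unreachable"),
    margin_eV = band$max_photon_energy - asymptote_rel_energy,
    stringsAsFactors = FALSE
  )
}

#' Gap between an asymptote energy and a spectral feature
#'
#' Absolute difference between a radical-asymptote relative energy and an
#' observed spectral feature energy (e.g. the maximum of a transient
#' absorption spectrum), used to judge whether the feature can be assigned to
#' the homolytic-cleavage threshold.
#'
#' @param asymptote_rel_energy Asymptote energy, eV.
#' @param spectral_feature_energy Feature energy, eV.
#' @param digits Rounding applied to the reported gap (default 2, the usual
#'   display precision); use `NULL` for full precision.
#' @return The absolute gap in eV.
#' @examples
#' gap_to_reference_energy(3.43, 3.49)  # 0.06
#' @export
gap_to_reference_energy <- function(asymptote_rel_energy,
                                    spectral_feature_energy,
                                    digits = 2) {
  stopifnot(is.numeric(asymptote_rel_energy),
            is.numeric(spectral_feature_energy),
            all(is.finite(asymptote_rel_energy)),
            all(is.finite(spectral_feature_energy)))
  g <- abs(spectral_feature_energy - asymptote_rel_energy)
  if (!is.null(digits)) g <- round(g, digits)
  g
}
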