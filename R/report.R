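# Pipeline assembly: ledger -> feasibility -> channel characterization ->
# kinetics, emitted as a machine-readable (JSON) and human-readable
# (Markdown) report. This is the programmatic surface behind the
# command-line script shipped in inst/cli/radikin.R.

#' Read a kinetics configuration file
#'
#' YAML (or JSON) file with optional blocks `tst`, `marcus` and
#' `landau_zener`. Couplings may be given in cm^-1 or eV via an explicit
#' `coupling_unit` key inside the block.
#'
#' @param path Path to the config file.
#' @return A named list of parameter blocks.
#' @export
read_kinetics_config <- function(path) {
  if (!file.exists(path)) stop("kinetics config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("tst", "marcus", "landau_zener", "photon_boost")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown kinetics config block(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

.run_kinetics_blocks <- function(cfg) {
  out <- list()
  if (!is.null(cfg$photon_boost)) {
    b <- cfg$photon_boost
    out$photon_boost <- do.call(photon_boost_series, b)
  }
  if (!is.null(cfg$tst)) {
    b <- cfg$tst
    r <- do.call(tst_rate, b)
    out$tst <- list(value = r$value, unit = r$unit,
                    exponent = r$exponent_diagnostic)
  }
  if (!is.null(cfg$marcus)) {
    b <- cfg$marcus
    r <- do.call(marcus_isc_rate, b)
    out$marcus <- list(value = r$value, unit = r$unit,
                       exponent = r$exponent_diagnostic)
  }
  if (!is.null(cfg$landau_zener)) {
    b <- cfg$landau_zener
    r <- do.call(landau_zener_probability, b)
    out$landau_zener <- list(value = r$value, unit = r$unit,
                             exponent = r$exponent_diagnostic)
  }
  out
}

#' Run the full two-step radical-reaction analysis
#'
#' Chains the stages of the analysis for one molecule: build the
#' relative-energy table from a species ledger, gate every radical asymptote
#' against each radiation band, characterize any supplied 1-D recombination
#' scans, and evaluate optional kinetics blocks. The scan stage is optional:
#' with no scans the report contains the ledger and feasibility sections
#' only.
#'
#' @param ledger A [species_ledger()], or a path to a ledger CSV (then
#'   `reference` is required).
#' @param reference Reference species label (only when `ledger` is a path).
#' @param bands A list of [radiation_band()] objects (or a single one).
#' @param scans Optional named list of [potential_curve()] objects or paths
#'   to scan CSV files (each may contain several state columns).
#' @param kinetics Optional kinetics config: a list as returned by
#'   [read_kinetics_config()] or a path to a YAML file.
#' @param molecule Molecule name recorded in the report.
#' @param use_zpe Use ZPE-corrected energies for the relative table.
#' @return An object of class `analysis_report` with elements `molecule`,
#'   `relative_energy_table`, `feasibility`, `channels`, `kinetics`,
#'   `provenance`.
#' @examples
#' rep <- run_full_analysis(make_ledger_fixture("table1"),
#'                          bands = radiation_band("UVA", 3.89))
#' rep$feasibility
#' @export
run_full_analysis <- function(ledger, reference = NULL,
                              bands = radiation_band("UVA", 3.89),
                              scans = NULL, kinetics = NULL,
                              molecule = "molecule", use_zpe = TRUE) {
  inputs <- list()
  if (is.character(ledger)) {
    if (is.null(reference)) {
      stop("a reference label is required when the ledger is given as a path",
           call. = FALSE)
    }
    inputs$ledger_path <- ledger
    ledger <- read_species_ledger(ledger, reference)
  }
  stopifnot(inherits(ledger, "species_ledger"))
  if (inherits(bands, "radiation_band")) bands <- list(bands)
  stopifnot(all(vapply(bands, inherits, logical(1), "radiation_band")))

  rel <- relative_energies(ledger, use_zpe = use_zpe)
  asy <- rel[rel$role == "radical_asymptote", , drop = FALSE]
  feas <- do.call(rbind, lapply(bands, function(b) {
    f <- feasibility_gate(asy$rel_energy_eV, b)
    cbind(label = asy$label, f, stringsAsFactors = FALSE)
  }))
  rownames(feas) <- NULL

  channels <- list()
  if (!is.null(scans)) {
    if (inherits(scans, "potential_curve")) scans <- list(scans)
    for (s in scans) {
      curves <- if (is.character(s)) {
        inputs$scan_paths <- c(inputs$scan_paths, s)
        read_scan(s)
      } else list(s)
      for (cv in curves) {
        channels[[cv$state_label]] <- characterize_channel(cv)
      }
    }
  }

  kin <- NULL
  if (!is.null(kinetics)) {
    if (is.character(kinetics)) {
      inputs$kinetics_path <- kinetics
      kinetics <- read_kinetics_config(kinetics)
    }
    kin <- .run_kinetics_blocks(kinetics)
  }

  structure(list(
    molecule = molecule,
    relative_energy_table = rel,
    feasibility = feas,
    channels = channels,
    kinetics = kin,
    provenance = list(
      package_version = as.character(utils::packageVersion("radikin")),
      reference = ledger$reference,
      use_zpe = isTRUE(use_zpe),
      bands = lapply(bands, function(b) unclass(b)),
      inputs = inputs,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Analysis report:", x$molecule, "==\n\n")
  print(x$relative_energy_table)
  cat("\nFeasibility of radical asymptotes:\n")
  print(x$feasibility, row.names = FALSE)
  if (length(x$channels)) {
    cat("\nChannels:\n")
    for (ch in x$channels) print(ch)
  }
  if (!is.null(x$kinetics)) {
    cat("\nKinetics:\n")
    utils::str(x$kinetics, give.attr = FALSE)
  }
  invisible(x)
}

# strip classes so jsonlite serializes plainly; drop the volatile timestamp
# when a byte-stable document is requested
.report_as_list <- function(report, drop_timestamp = FALSE) {
  ch <- lapply(report$channels, function(c0) {
    list(state_label = c0$state_label, multiplicity = c0$multiplicity,
         classification = c0$classification,
         barrier_height = c0$barrier_height, well_depth = c0$well_depth,
         asymptote_energy = c0$asymptote_energy,
         stationary_points = c0$stationary_points)
  })
  prov <- report$provenance
  if (drop_timestamp) prov$timestamp <- NULL
  list(molecule = report$molecule,
       relative_energy_table = as.data.frame(report$relative_energy_table),
       feasibility = report$feasibility,
       channels = ch,
       kinetics = report$kinetics,
       provenance = prov)
}

#' Write an analysis report
#'
#' `write_report_json()` emits the machine surface (JSON; deterministic —
#' byte-identical for identical inputs when `drop_timestamp = TRUE`);
#' `write_report_markdown()` emits a human-readable summary.
#'
#' @param report An `analysis_report`.
#' @param path Output file path.
#' @param drop_timestamp Exclude the volatile timestamp field (JSON only).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, drop_timestamp = FALSE) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(.report_as_list(report, drop_timestamp), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_markdown <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  rel <- report$relative_energy_table
  lines <- c(
    paste("#", report$molecule, "two-step radical reaction analysis"),
    "",
    sprintf("Reference species: %s (%s)", attr(rel, "reference"),
            if (isTRUE(attr(rel, "use_zpe"))) "ZPE-corrected" else "electronic"),
    "",
    "## Relative energies",
    "",
    "| species | multiplicity | role | eV | kcal/mol |",
    "|---|---|---|---:|---:|",
    sprintf("| %s | %s | %s | %.2f | %.1f |", rel$label, rel$multiplicity,
            rel$role, rel$rel_energy_eV, rel$rel_energy_kcal),
    "",
    "## Feasibility of radical asymptotes",
    "",
    "| species | band | asymptote (eV) | verdict | margin (eV) |",
    "|---|---|---:|---|---:|",
    sprintf("| %s | %s | %.2f | %s | %+.2f |",
            report$feasibility$label, report$feasibility$band,
            report$feasibility$asymptote_eV, report$feasibility$verdict,
            report$feasibility$margin_eV)
  )
  if (length(report$channels)) {
    lines <- c(lines, "", "## Channels", "",
               "| state | multiplicity | class | barrier (eV) | well depth (eV) |",
               "|---|---|---|---:|---:|",
               vapply(report$channels, function(c0) {
                 sprintf("| %s | %s | %s | %.3f | %.3f |", c0$state_label,
                         c0$multiplicity, c0$classification,
                         c0$barrier_height, c0$well_depth)
               }, character(1)))
  }
  if (!is.null(report$kinetics)) {
    lines <- c(lines, "", "## Kinetics", "",
               "```", utils::capture.output(utils::str(report$kinetics)), "```")
  }
  writeLines(lines, path)
  invisible(path)
}
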