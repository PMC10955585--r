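# Synthetic 1-D channels and crossing pairs with known ground truth.
#
# The smooth channel shape is a Morse well plus a Gaussian barrier bump:
#   E(r) = A_well * [ (1 - e^{-a (r - r_w)})^2 - 1 ] + A_bar * e^{-(r-r_b)^2 / 2s^2}
# relative to the asymptote. Because the two terms overlap, the amplitudes
# are calibrated by a fixed-point loop so that the *composite* curve's
# extremum energies match the requested well depth and barrier height to
# better than 1e-6 eV; the calibrated extremum locations and energies are
# returned as ground truth.

.default_synth_seed <- 20240308

# evaluate the smooth channel at arbitrary r
.channel_fun <- function(a_well, a_bar, morse_a, r_w, r_b, sigma, asymptote) {
  function(r) {
    asymptote +
      a_well * ((1 - exp(-morse_a * (r - r_w)))^2 - 1) +
      (if (a_bar != 0) a_bar * exp(-(r - r_b)^2 / (2 * sigma^2)) else 0)
  }
}

# bracket an extremum on a dense grid, then refine locally; optimize() alone
# can step over a narrow bump on a wide interval
.refine_extremum <- function(f, lo, hi, maximum) {
  dense <- seq(lo, hi, length.out = 2000L)
  vals <- f(dense)
  i <- if (maximum) which.max(vals) else which.min(vals)
  a <- dense[max(i - 1L, 1L)]
  b <- dense[min(i + 1L, length(dense))]
  o <- stats::optimize(f, c(a, b), maximum = maximum, tol = 1e-12)
  if (maximum) c(o$maximum, o$objective) else c(o$minimum, o$objective)
}

# run RNG-dependent code under a seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic recombination channel
#'
#' Builds a smooth 1-D potential curve emulating a radical-recombination
#' scan: a product well at short range (`well_position`), optionally guarded
#' by a barrier bump at `barrier_position`, decaying to the radical asymptote
#' at large separation. The functional form is a Morse well plus a Gaussian
#' bump whose amplitudes are calibrated so the composite curve's minimum lies
#' exactly `well_depth` below the asymptote and its maximum exactly
#' `barrier_height` above it (to 1e-6 eV). Gaussian noise of standard
#' deviation `noise_sd` is added point-wise under the given seed; the ground
#' truth (noise-free extrema) is returned alongside and is independent of
#' the seed.
#'
#' @param asymptote_energy Energy of the separated-fragment limit, eV.
#' @param well_depth Depth of the product well below the asymptote, eV
#'   (>= 0; 0 gives a flat-bottomed curve).
#' @param barrier_height Barrier above the asymptote, eV (0 = barrierless).
#' @param well_position,barrier_position Extremum locations, angstrom; must
#'   satisfy `well_position < barrier_position < r_max`.
#' @param r_min,r_max,step Coordinate grid, angstrom; at least 10 points.
#' @param noise_sd Standard deviation of additive Gaussian noise, eV.
#' @param seed Integer seed for the noise (default 20240308).
#' @param morse_a Morse range parameter, 1/angstrom.
#' @param sigma Gaussian barrier width, angstrom.
#' @param state_label,multiplicity Passed to [potential_curve()].
#' @return A list of class `synthetic_channel` with elements `curve` (a
#'   [potential_curve()]) and `truth` (list: `classification`,
#'   `barrier_height`, `well_depth`, `barrier_position`, `well_position`,
#'   `asymptote_energy` — all measured on the calibrated smooth curve).
#' @examples
#' ch <- make_channel(well_depth = 0.9, barrier_height = 0.4, noise_sd = 0)
#' characterize_channel(ch$curve)
#' @export
make_channel <- function(asymptote_energy = 0,
                         well_depth = 0.9,
                         barrier_height = 0,
                         well_position = 1.1,
                         barrier_position = 1.8,
                         r_min = 0.8, r_max = 4, step = 0.02,
                         noise_sd = 0,
                         seed = .default_synth_seed,
                         morse_a = 2.2, sigma = 0.15,
                         state_label = "synthetic",
                         multiplicity = "triplet") {
  if (step <= 0) stop("grid step must be positive", call. = FALSE)
  r <- seq(r_min, r_max, by = step)
  if (length(r) < 10L) stop("grid must contain at least 10 points", call. = FALSE)
  stopifnot(well_depth >= 0, barrier_height >= 0, noise_sd >= 0)
  if (!(well_position < barrier_position && barrier_position < r_max)) {
    stop("require well_position < barrier_position < r_max", call. = FALSE)
  }

  a_well <- well_depth
  a_bar <- barrier_height
  truth_min <- c(well_position, asymptote_energy - well_depth)
  truth_max <- c(barrier_position, asymptote_energy + barrier_height)
  if (well_depth > 0 || barrier_height > 0) {
    for (it in seq_len(200)) {
      f <- .channel_fun(a_well, a_bar, morse_a, well_position,
                        barrier_position, sigma, asymptote_energy)
      err <- 0
      if (well_depth > 0) {
        om <- .refine_extremum(f, r_min, barrier_position, maximum = FALSE)
        e_min <- om[2]
        err <- max(err, abs(e_min - (asymptote_energy - well_depth)))
        a_well <- a_well + (e_min - (asymptote_energy - well_depth))
        truth_min <- om
      }
      if (barrier_height > 0) {
        oM <- .refine_extremum(f, well_position, r_max, maximum = TRUE)
        e_max <- oM[2]
        err <- max(err, abs(e_max - (asymptote_energy + barrier_height)))
        a_bar <- a_bar - (e_max - (asymptote_energy + barrier_height))
        truth_max <- oM
      }
      if (err < 1e-9) break
    }
  }
  f <- .channel_fun(a_well, a_bar, morse_a, well_position,
                    barrier_position, sigma, asymptote_energy)
  energy <- f(r)
  if (noise_sd > 0) {
    energy <- energy + .with_seed(seed, stats::rnorm(length(r), 0, noise_sd))
  }
  truth <- list(
    classification = if (barrier_height > 0) "activated" else "barrierless",
    barrier_height = barrier_height,
    well_depth = well_depth,
    barrier_position = if (barrier_height > 0) truth_max[1] else NA_real_,
    well_position = if (well_depth > 0) truth_min[1] else NA_real_,
    asymptote_energy = asymptote_energy
  )
  structure(list(curve = potential_curve(r, energy, state_label, multiplicity),
                 truth = truth),
            class = "synthetic_channel")
}

#' @export
print.synthetic_channel <- function(x, ...) {
  t <- x$truth
  cat(sprintf("Synthetic channel (%s): well %.3f eV at %.3f A, barrier %.3f eV%s\n",
              t$classification, t$well_depth,
              if (is.na(t$well_position)) NA else t$well_position,
              t$barrier_height,
              if (is.na(t$barrier_position)) ""
              else sprintf(" at %.3f A", t$barrier_position)))
  print(x$curve)
  invisible(x)
}

#' Generate a pair of curves with a known crossing
#'
#' Produces two potential curves of different multiplicity with an
#' analytically known intersection, for validating [find_crossings()]. The
#' default form is linear, `E = offset + slope * r`, whose crossing is the
#' closed-form root `(offset_b - offset_a) / (slope_a - slope_b)`; the
#' `"morse"` form uses two displaced Morse wells whose crossing ground truth
#' is localized by dense evaluation of the smooth difference (grid of 1e6
#' points refined by root bracketing).
#'
#' @param offset_a,slope_a,offset_b,slope_b Linear parameters (eV and
#'   eV/angstrom). For the Morse form, `offset_*` is the well minimum energy
#'   and `slope_*` is re-interpreted as the well position, angstrom.
#' @param r_min,r_max,step Shared coordinate grid, angstrom.
#' @param form `"linear"` (default) or `"morse"`.
#' @param depth_a,depth_b,morse_a_par Morse depths (eV) and range parameter.
#' @return A list of class `crossing_pair` with `curve_a`, `curve_b` (labels
#'   `"S"`/`"T"`, singlet/triplet) and `truth` (data.frame of crossing
#'   `coordinate` and `energy`; zero rows if the curves do not cross on the
#'   grid span).
#' @examples
#' cp <- make_crossing_pair(0, 1, 2, -1, r_min = 0, r_max = 2, step = 0.1)
#' cp$truth
#' @export
make_crossing_pair <- function(offset_a, slope_a, offset_b, slope_b,
                               r_min = 0, r_max = 4, step = 0.02,
                               form = c("linear", "morse"),
                               depth_a = 2, depth_b = 1, morse_a_par = 1.5) {
  form <- match.arg(form)
  if (step <= 0) stop("grid step must be positive", call. = FALSE)
  r <- seq(r_min, r_max, by = step)
  if (length(r) < 4L) stop("grid must contain at least 4 points", call. = FALSE)
  if (form == "linear") {
    if (slope_a == slope_b) {
      stop("parallel lines never cross transversally", call. = FALSE)
    }
    fa <- function(r) offset_a + slope_a * r
    fb <- function(r) offset_b + slope_b * r
    rc <- (offset_b - offset_a) / (slope_a - slope_b)
    truth <- if (rc >= r_min && rc <= r_max) {
      data.frame(coordinate = rc, energy = fa(rc))
    } else data.frame(coordinate = numeric(0), energy = numeric(0))
  } else {
    fa <- function(r) offset_a + depth_a * (1 - exp(-morse_a_par * (r - slope_a)))^2
    fb <- function(r) offset_b + depth_b * (1 - exp(-morse_a_par * (r - slope_b)))^2
    # dense-evaluation oracle for the smooth intersection
    dense <- seq(r_min, r_max, length.out = 1e6)
    dd <- fa(dense) - fb(dense)
    sc <- which(dd[-1] * dd[-length(dd)] < 0)
    roots <- vapply(sc, function(i) {
      stats::uniroot(function(z) fa(z) - fb(z),
                     c(dense[i], dense[i + 1]), tol = 1e-12)$root
    }, numeric(1))
    truth <- data.frame(coordinate = roots, energy = fa(roots))
    truth <- truth[order(truth$energy), , drop = FALSE]
    rownames(truth) <- NULL
  }
  structure(list(
    curve_a = potential_curve(r, fa(r), "S", "singlet"),
    curve_b = potential_curve(r, fb(r), "T", "triplet"),
    truth = truth
  ), class = "crossing_pair")
}

# frozen md5 checksums of the installed ledger fixtures
.fixture_md5 <- c(
  thiocytosine_table1 = "5a84ec40fd63cf46e473858fdaf112cb",
  cytosine_table4 = "22ae3961a800c636ebb87fed38a8247e"
)

#' Load a shipped species-ledger fixture
#'
#' Returns one of the two reference ledgers installed with the package:
#' `"table1"`, ZPE-corrected CASPT2 energies for the four lowest singlet
#' tautomers of 2-thiocytosine plus its singlet/triplet radical asymptotes
#' (reference: the amino-thiol tautomer TC2); or `"table4"`, the analogous
#' ledger for cytosine (reference: the amino-hydroxo tautomer C2). The files
#' are checksum-verified on load.
#'
#' @param which `"table1"` (2-thiocytosine) or `"table4"` (cytosine).
#' @return A [species_ledger()] with 8 records.
#' @examples
#' relative_energies(make_ledger_fixture("table1"))
#' @export
make_ledger_fixture <- function(which = c("table1", "table4")) {
  which <- match.arg(which)
  file <- switch(which,
                 table1 = "thiocytosine_table1.csv",
                 table4 = "cytosine_table4.csv")
  ref <- switch(which, table1 = "TC2", table4 = "C2")
  path <- system.file("extdata", file, package = "radikin", mustWork = TRUE)
  key <- sub("\\.csv$", "", file)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.fixture_md5[[key]]))) {
    stop("fixture ", file, " failed its checksum; installation is corrupted",
         call. = FALSE)
  }
  read_species_ledger(path, reference = ref)
}
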