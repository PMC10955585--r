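#' One-dimensional potential-energy curve
#'
#' A scan of an electronic state's energy along a single nuclear coordinate,
#' here the distance (in angstrom) between an attacking hydrogen atom and the
#' attacked atom of the heavy radical. The coordinate grid must be strictly
#' increasing with at least 4 points; increasing coordinate means separating
#' fragments, so recombination channels are read right to left.
#'
#' @param r Strictly increasing numeric coordinate grid, angstrom.
#' @param energy Numeric energies per grid point, eV, relative to a declared
#'   reference (usually the ground-state minimum or the radical asymptote).
#' @param state_label Name of the electronic state (e.g. `"S0"`, `"T1"`).
#' @param multiplicity One of `"singlet"`, `"doublet_pair"`, `"triplet"`.
#' @return An object of class `potential_curve`.
#' @seealso [find_stationary_points()], [characterize_channel()],
#'   [find_crossings()], [read_scan()]
#' @export
potential_curve <- function(r, energy, state_label = "state",
                            multiplicity = c("singlet", "doublet_pair", "triplet")) {
  multiplicity <- match.arg(multiplicity)
  stopifnot(is.numeric(r), is.numeric(energy))
  if (length(r) != length(energy)) {
    stop("coordinate and energy must have equal length", call. = FALSE)
  }
  if (length(r) < 4L) {
    stop("a potential curve needs at least 4 grid points", call. = FALSE)
  }
  if (any(!is.finite(r)) || any(!is.finite(energy))) {
    stop("coordinate and energy must be finite", call. = FALSE)
  }
  if (any(diff(r) <= 0)) {
    stop("coordinate grid must be strictly increasing", call. = FALSE)
  }
  structure(list(r = as.numeric(r), energy = as.numeric(energy),
                 state_label = as.character(state_label)[1],
                 multiplicity = multiplicity),
            class = "potential_curve")
}

#' @export
print.potential_curve <- function(x, ...) {
  cat(sprintf("Potential curve %s (%s): %d points, r in [%.3f, %.3f] A, E in [%.4f, %.4f] eV\n",
              x$state_label, x$multiplicity, length(x$r),
              min(x$r), max(x$r), min(x$energy), max(x$energy)))
  invisible(x)
}

#' @export
plot.potential_curve <- function(x, ...,
                                 xlab = "r (Å)", ylab = "E (eV)",
                                 type = "l") {
  graphics::plot(x$r, x$energy, type = type, xlab = xlab, ylab = ylab,
                 main = x$state_label, ...)
  invisible(x)
}

#' Read / write potential-energy scans
#'
#' Delimited-text scan format: header `r_angstrom,<label>:<multiplicity>[,...]`
#' with one energy column per electronic state. `read_scan()` validates the
#' monotone grid and returns one [potential_curve()] per state column;
#' `write_scan()` emits the same layout.
#'
#' @param path File path.
#' @return `read_scan()`: a named list of [potential_curve()] objects.
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop("scan file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L || names(tab)[1] != "r_angstrom") {
    stop("scan file must start with an 'r_angstrom' column followed by state columns",
         call. = FALSE)
  }
  r <- tab[[1]]
  curves <- list()
  for (j in seq(2L, ncol(tab))) {
    parts <- strsplit(names(tab)[j], ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("state column '", names(tab)[j],
           "' is not of the form <label>:<multiplicity>", call. = FALSE)
    }
    curves[[parts[1]]] <- potential_curve(r, tab[[j]], state_label = parts[1],
                                          multiplicity = parts[2])
  }
  curves
}

#' @param curves A list of [potential_curve()] objects on a common grid.
#' @rdname read_scan
#' @export
write_scan <- function(curves, path) {
  if (inherits(curves, "potential_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L)
  r <- curves[[1]]$r
  cols <- lapply(curves, function(cv) {
    if (!isTRUE(all.equal(cv$r, r))) {
      stop("all curves must share the same coordinate grid to be written together",
           call. = FALSE)
    }
    cv$energy
  })
  names(cols) <- vapply(curves, function(cv)
    paste0(cv$state_label, ":", cv$multiplicity), character(1))
  tab <- data.frame(r_angstrom = r, cols, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# quadratic vertex through three points; returns c(r*, E*) or NA if the
# parabola is degenerate (collinear points)
.quad_vertex <- function(r, e) {
  # Lagrange second-difference form on a possibly non-uniform grid
  d21 <- (e[2] - e[1]) / (r[2] - r[1])
  d32 <- (e[3] - e[2]) / (r[3] - r[2])
  a <- (d32 - d21) / (r[3] - r[1])
  if (a == 0) return(c(NA_real_, NA_real_))
  b <- d21 - a * (r[1] + r[2])
  rv <- -b / (2 * a)
  ev <- e[1] + (rv - r[1]) * (d21 + a * (rv - r[2]))
  c(rv, ev)
}

#' Locate stationary points on a 1-D potential curve
#'
#' Interior sign changes of the finite-difference slope are reported as
#' minima or maxima; each is refined by a local quadratic fit through the
#' three bracketing grid points. Grid endpoints are never reported as
#' stationary. If the quadratic refinement lands outside the bracketing
#' interval the raw grid point is kept (`refinement = "grid"`).
#'
#' @param curve A [potential_curve()].
#' @return A data.frame with columns `kind` (`"minimum"`/`"maximum"`),
#'   `coordinate`, `energy`, `refinement`; zero rows if the curve is strictly
#'   monotone.
#' @examples
#' pc <- potential_curve(seq(1, 3, 0.1), (seq(1, 3, 0.1) - 2)^2)
#' find_stationary_points(pc)
#' @export
find_stationary_points <- function(curve) {
  stopifnot(inherits(curve, "potential_curve"))
  r <- curve$r; e <- curve$energy
  n <- length(r)
  d <- diff(e)
  kind <- character(0); coord <- numeric(0); en <- numeric(0); refn <- character(0)
  for (i in seq(2L, n - 1L)) {
    dl <- d[i - 1L]; dr <- d[i]
    k <- if (dl > 0 && dr < 0) "maximum"
         else if (dl < 0 && dr > 0) "minimum"
         else if (dl != 0 && dr == 0) NA_character_  # plateau edge: skip
         else NA_character_
    if (is.na(k)) next
    v <- .quad_vertex(r[(i - 1L):(i + 1L)], e[(i - 1L):(i + 1L)])
    if (is.finite(v[1]) && v[1] >= r[i - 1L] && v[1] <= r[i + 1L]) {
      coord <- c(coord, v[1]); en <- c(en, v[2]); refn <- c(refn, "quadratic")
    } else {
      coord <- c(coord, r[i]); en <- c(en, e[i]); refn <- c(refn, "grid")
    }
    kind <- c(kind, k)
  }
  data.frame(kind = kind, coordinate = coord, energy = en,
             refinement = refn, stringsAsFactors = FALSE)
}

#' Characterize a recombination channel
#'
#' Classifies a 1-D recombination channel as barrierless or activated and
#' measures its barrier height and well depth relative to the radical
#' asymptote. The asymptote energy defaults to the curve's last (largest
#' coordinate) grid value, i.e. the separated-fragment limit.
#'
#' A channel is barrierless when no interior maximum exceeds the asymptote by
#' more than `barrier_tol`; the barrier height is the largest interior
#' maximum above the asymptote (clamped at 0), and the well depth is the
#' asymptote energy minus the deepest point of the curve. A curve that never
#' dips below the asymptote but rises above it at short range carries no
#' bound product and is flagged `"repulsive"` with both measures `NA`.
#'
#' @param curve A [potential_curve()].
#' @param asymptote_energy Energy of the separated-fragment limit, eV;
#'   default: the last grid point.
#' @param barrier_tol Tolerance (eV) above the asymptote below which an
#'   interior maximum is not counted as a barrier. Default 0.005 eV.
#' @return An object of class `channel_characterization`: a list with
#'   `classification` (`"barrierless"`, `"activated"` or `"repulsive"`),
#'   `barrier_height`, `well_depth` (both eV, `NA` when repulsive),
#'   `asymptote_energy`, `stationary_points`, and the curve's identity.
#' @examples
#' r <- seq(0.8, 4, 0.02)
#' pc <- potential_curve(r, -2 * exp(-2 * (r - 1.1)))
#' characterize_channel(pc)
#' @export
characterize_channel <- function(curve, asymptote_energy = NULL,
                                 barrier_tol = 0.005) {
  stopifnot(inherits(curve, "potential_curve"))
  e <- curve$energy
  if (is.null(asymptote_energy)) asymptote_energy <- e[length(e)]
  sp <- find_stationary_points(curve)
  maxima <- sp[sp$kind == "maximum", , drop = FALSE]
  minima <- sp[sp$kind == "minimum", , drop = FALSE]
  # deepest point: refined interior minimum if present, else the sampled grid
  deepest <- min(c(e, minima$energy))
  has_well <- deepest < asymptote_energy - barrier_tol
  repulsive <- !has_well && !nrow(minima) && e[1] > asymptote_energy + barrier_tol
  if (repulsive) {
    classification <- "repulsive"
    barrier_height <- NA_real_
    well_depth <- NA_real_
  } else {
    top <- if (nrow(maxima)) max(maxima$energy) else -Inf
    activated <- top > asymptote_energy + barrier_tol
    classification <- if (activated) "activated" else "barrierless"
    barrier_height <- max(top - asymptote_energy, 0)
    well_depth <- asymptote_energy - deepest
  }
  structure(list(
    state_label = curve$state_label,
    multiplicity = curve$multiplicity,
    classification = classification,
    barrier_height = barrier_height,
    well_depth = well_depth,
    asymptote_energy = asymptote_energy,
    barrier_tol = barrier_tol,
    stationary_points = sp,
    curve = curve
  ), class = "channel_characterization")
}

#' @export
print.channel_characterization <- function(x, ...) {
  cat(sprintf("Channel %s (%s): %s\n", x$state_label, x$multiplicity,
              x$classification))
  if (x$classification != "repulsive") {
    cat(sprintf("  barrier height: %.4f eV above asymptote\n", x$barrier_height))
    cat(sprintf("  well depth:     %.4f eV below asymptote\n", x$well_depth))
  }
  cat(sprintf("  asymptote:      %.4f eV\n", x$asymptote_energy))
  invisible(x)
}

#' @export
summary.channel_characterization <- function(object, ...) {
  print(object)
  if (nrow(object$stationary_points)) {
    cat("  stationary points:\n")
    print(object$stationary_points, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.channel_characterization <- function(x, ...) {
  plot(x$curve, ...)
  graphics::abline(h = x$asymptote_energy, lty = 2, col = "grey50")
  sp <- x$stationary_points
  if (nrow(sp)) {
    graphics::points(sp$coordinate, sp$energy,
                     pch = ifelse(sp$kind == "maximum", 24, 25),
                     bg = ifelse(sp$kind == "maximum", "firebrick", "steelblue"))
  }
  invisible(x)
}

#' Localize crossings between two potential curves
#'
#' Finds the transversal intersections of two curves of (typically)
#' different spin multiplicity. Both curves are linearly re-interpolated
#' onto the union grid restricted to their common coordinate span; every sign
#' change of the energy difference is localized by linear interpolation
#' between the bracketing points, and the slope of each curve at the crossing
#' is estimated by central differences. Grid points where the difference is
#' exactly zero without a sign change (touching) are excluded.
#'
#' Crossings are returned sorted by increasing energy, so the first row is
#' the lowest-lying crossing.
#'
#' @param curve_a,curve_b [potential_curve()] objects with overlapping
#'   coordinate spans.
#' @return A data.frame of class `crossing_points` with columns `coordinate`,
#'   `energy`, `slope_a`, `slope_b` (eV/angstrom); zero rows if the curves do
#'   not cross.
#' @examples
#' r <- seq(0, 2, 0.1)
#' a <- potential_curve(r, r, "S0", "singlet")
#' b <- potential_curve(r, 2 - r, "T1", "triplet")
#' find_crossings(a, b)
#' @export
find_crossings <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "potential_curve"),
            inherits(curve_b, "potential_curve"))
  lo <- max(min(curve_a$r), min(curve_b$r))
  hi <- min(max(curve_a$r), max(curve_b$r))
  if (lo >= hi) {
    stop("curves have disjoint coordinate spans; no common window to search",
         call. = FALSE)
  }
  grid <- sort(unique(c(curve_a$r, curve_b$r)))
  grid <- grid[grid >= lo & grid <= hi]
  ea <- stats::approx(curve_a$r, curve_a$energy, xout = grid)$y
  eb <- stats::approx(curve_b$r, curve_b$energy, xout = grid)$y
  d <- ea - eb
  if (all(abs(d) < .Machine$double.eps * 100)) {
    stop("curves are identical over the common span; no transversal crossing defined",
         call. = FALSE)
  }
  slope_at <- function(r0, rr, ee) {
    # central difference on the sampled curve around r0
    i <- findInterval(r0, rr)
    i <- min(max(i, 2L), length(rr) - 1L)
    (ee[i + 1L] - ee[i - 1L]) / (rr[i + 1L] - rr[i - 1L])
  }
  coord <- numeric(0); en <- numeric(0); sa <- numeric(0); sb <- numeric(0)
  for (i in seq_len(length(grid) - 1L)) {
    d1 <- d[i]; d2 <- d[i + 1L]
    hit <- NA_real_
    if (d1 == 0) {
      # counted only when the sign genuinely changes across the zero
      if (i > 1L && sign(d[i - 1L]) * sign(d2) < 0) hit <- grid[i]
    } else if (sign(d1) * sign(d2) < 0) {
      hit <- grid[i] - d1 * (grid[i + 1L] - grid[i]) / (d2 - d1)
    }
    if (is.finite(hit)) {
      coord <- c(coord, hit)
      en <- c(en, stats::approx(grid, ea, xout = hit)$y)
      sa <- c(sa, slope_at(hit, grid, ea))
      sb <- c(sb, slope_at(hit, grid, eb))
    }
  }
  out <- data.frame(coordinate = coord, energy = en,
                    slope_a = sa, slope_b = sb)
  out <- out[order(out$energy), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("crossing_points", "data.frame")
  out
}
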