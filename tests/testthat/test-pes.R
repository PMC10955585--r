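test_that("stationary points of a sampled parabola are refined to the vertex", {
  r <- seq(1, 3, by = 0.1)
  sp <- find_stationary_points(potential_curve(r, (r - 2)^2))
  expect_equal(nrow(sp), 1L)
  expect_identical(sp$kind, "minimum")
  expect_equal(sp$coordinate, 2, tolerance = 1e-9)
  expect_equal(sp$energy, 0, tolerance = 1e-9)
  expect_identical(sp$refinement, "quadratic")
})

test_that("monotone curves carry no stationary points and endpoints are excluded", {
  r <- seq(0, 2, by = 0.1)
  expect_equal(nrow(find_stationary_points(potential_curve(r, -r))), 0L)
  # minimum exactly at an endpoint must not be reported
  expect_equal(nrow(find_stationary_points(potential_curve(r, (r - 2)^2))), 0L)
})

test_that("stationary energies are invariant under coordinate shift and energy offset", {
  ch <- make_channel(well_depth = 1.2, barrier_height = 0.3, noise_sd = 0)
  sp0 <- find_stationary_points(ch$curve)
  shifted <- potential_curve(ch$curve$r + 5, ch$curve$energy + 2.5,
                             "shifted", "triplet")
  sp1 <- find_stationary_points(shifted)
  expect_equal(sp1$energy - 2.5, sp0$energy, tolerance = 1e-9)
  expect_equal(sp1$coordinate - 5, sp0$coordinate, tolerance = 1e-9)
})

test_that("channel characterization matches generator ground truth", {
  ch <- make_channel(well_depth = 0.9, barrier_height = 0.4, noise_sd = 0)
  cc <- characterize_channel(ch$curve, asymptote_energy = 0)
  expect_identical(cc$classification, "activated")
  expect_equal(cc$barrier_height, 0.4, tolerance = 0.01)
  expect_equal(cc$well_depth, 0.9, tolerance = 0.01)

  ch31 <- make_channel(well_depth = 0.82, barrier_height = 0.31, noise_sd = 0)
  cc31 <- characterize_channel(ch31$curve, asymptote_energy = 0)
  expect_identical(cc31$classification, "activated")
  expect_equal(cc31$barrier_height, 0.31, tolerance = 0.01)

  downhill <- make_channel(well_depth = 3.43, barrier_height = 0, noise_sd = 0)
  ccd <- characterize_channel(downhill$curve, asymptote_energy = 0)
  expect_identical(ccd$classification, "barrierless")
  expect_identical(ccd$barrier_height, 0)
  expect_equal(ccd$well_depth, 3.43, tolerance = 0.01)
})

test_that("degenerate channels are classified sensibly", {
  r <- seq(0.8, 4, by = 0.02)
  flat <- characterize_channel(potential_curve(r, rep(1.5, length(r))))
  expect_identical(flat$classification, "barrierless")
  expect_identical(flat$barrier_height, 0)
  expect_identical(flat$well_depth, 0)
  # purely repulsive wall decaying to the asymptote: no bound product
  rep_ch <- characterize_channel(potential_curve(r, 2 * exp(-2 * (r - 0.8))))
  expect_identical(rep_ch$classification, "repulsive")
  expect_true(is.na(rep_ch$barrier_height) && is.na(rep_ch$well_depth))
})

test_that("linear curves cross where algebra says, with correct slopes", {
  r <- seq(0, 2, by = 0.1)
  a <- potential_curve(r, r, "S0", "singlet")
  b <- potential_curve(r, 2 - r, "T1", "triplet")
  x <- find_crossings(a, b)
  expect_equal(nrow(x), 1L)
  expect_equal(x$coordinate, 1)
  expect_equal(x$energy, 1)
  expect_equal(x$slope_a, 1)
  expect_equal(x$slope_b, -1)
  # symmetry up to slope label swap
  y <- find_crossings(b, a)
  expect_equal(y$coordinate, x$coordinate)
  expect_equal(y$slope_a, x$slope_b)
  expect_equal(y$slope_b, x$slope_a)
})

test_that("degenerate and disjoint crossing inputs are rejected", {
  r <- seq(0, 2, by = 0.1)
  a <- potential_curve(r, r, "S0", "singlet")
  expect_error(find_crossings(a, a), "identical")
  far <- potential_curve(r + 10, r, "T1", "triplet")
  expect_error(find_crossings(a, far), "disjoint")
})

test_that("crossing count equals the sign changes of the sampled difference", {
  set.seed(7)
  r <- seq(0, 4, by = 0.05)
  for (i in 1:25) {
    ea <- cumsum(stats::rnorm(length(r), 0, 0.05))
    eb <- cumsum(stats::rnorm(length(r), 0, 0.05))
    d <- ea - eb
    brute <- sum(d[-1] * d[-length(d)] < 0)
    found <- find_crossings(potential_curve(r, ea, "a", "singlet"),
                            potential_curve(r, eb, "b", "triplet"))
    expect_equal(nrow(found), brute)
    expect_false(is.unsorted(found$energy))
  }
})

test_that("a Morse-pair crossing is recovered within half a grid step and converges", {
  cp <- make_crossing_pair(0, 1.2, 0.8, 2.0, r_min = 0.5, r_max = 4,
                           step = 0.02, form = "morse",
                           depth_a = 2, depth_b = 1)
  expect_gt(nrow(cp$truth), 0L)
  found <- find_crossings(cp$curve_a, cp$curve_b)
  expect_equal(nrow(found), nrow(cp$truth))
  expect_lt(max(abs(found$coordinate - cp$truth$coordinate)), 0.01)
  # linear interpolation converges as the grid is refined
  cp2 <- make_crossing_pair(0, 1.2, 0.8, 2.0, r_min = 0.5, r_max = 4,
                            step = 0.005, form = "morse",
                            depth_a = 2, depth_b = 1)
  found2 <- find_crossings(cp2$curve_a, cp2$curve_b)
  expect_lt(max(abs(found2$coordinate - cp2$truth$coordinate)),
            max(abs(found$coordinate - cp$truth$coordinate)))
})

test_that("scan files round-trip through the reader and writer", {
  ch <- make_channel(well_depth = 0.9, barrier_height = 0.4, noise_sd = 0,
                     state_label = "T1", multiplicity = "triplet")
  ch2 <- make_channel(well_depth = 3.4, barrier_height = 0, noise_sd = 0,
                      state_label = "S0", multiplicity = "singlet")
  path <- withr::local_tempfile(fileext = ".csv")
  write_scan(list(ch$curve, ch2$curve), path)
  curves <- read_scan(path)
  expect_named(curves, c("T1", "S0"))
  expect_equal(curves$T1$energy, ch$curve$energy, tolerance = 1e-12)
  expect_identical(curves$S0$multiplicity, "singlet")
  # malformed headers are rejected
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("radius,T1:triplet", "1,0", "2,0", "3,0", "4,0"), bad)
  expect_error(read_scan(bad), "r_angstrom")
})

test_that("curves with bad grids are rejected", {
  expect_error(potential_curve(c(1, 2, 2, 3), 1:4), "strictly increasing")
  expect_error(potential_curve(1:3, 1:3), "at least 4")
  expect_error(potential_curve(1:4, c(1, 2, NA, 4)), "finite")
})
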