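test_that("RRHO factors reach their textbook limits", {
  # classical limit of a single harmonic mode: q_vib -> kBT/(h nu),
  # valid to 1% once kBT >= 50 h nu
  cst <- physical_constants()
  nu <- 3  # cm^-1
  kT_cm <- cst$k_B * 298.15 / (cst$hc * 1e-7)
  expect_gte(kT_cm, 50 * nu)
  q <- rrho_partition_functions(1, nu, numeric(0), 298.15)$q_vib
  expect_equal(q, kT_cm / nu, tolerance = 0.01)
  # ZPE-referenced convention: q_vib -> 1 as T -> 0
  q0 <- rrho_partition_functions(1, 2000, numeric(0), 1)$q_vib
  expect_equal(q0, 1, tolerance = 1e-12)
})

test_that("translational q of the H atom matches the closed-form SI oracle", {
  got <- rrho_partition_functions(1.008, numeric(0), numeric(0), 298.15,
                                  standard_concentration = 1)$q_trans
  expect_equal(got, oracle_translational_q(1.008, 298.15, 1),
               tolerance = 1e-10)
})

test_that("partition-function preconditions are enforced", {
  expect_error(rrho_partition_functions(1, c(100, -50), numeric(0), 300),
               "imaginary reaction mode")
  expect_error(rrho_partition_functions(1, 100, c(1, 2), 300), "length 0")
})

test_that("TST rate with the photon term cancelling the barrier is the prefactor", {
  barrier <- 0.5
  k <- tst_rate(q_ts = 2, q_fragment = 4, q_atom = 10,
                u_ts_0 = barrier, u_fragment_0 = 0, u_atom_0 = 0,
                x = 0.5, e_p = 1.0, temperature = 300)
  cst <- physical_constants()
  expect_equal(k$exponent_diagnostic, 0)
  expect_equal(k$value, (cst$k_B * 300 / cst$h) * 2 / (4 * 10))
})

test_that("log TST rate is linear in x with slope e_p/(kB T) and increases with T", {
  cst <- physical_constants()
  e_p <- 3.49; temp <- 298.15
  xs <- seq(0, 0.4, by = 0.05)
  ks <- vapply(xs, function(x)
    tst_rate(1, 1, 1, u_ts_0 = 2, u_fragment_0 = 0, u_atom_0 = 0,
             x = x, e_p = e_p, temperature = temp)$value, numeric(1))
  slopes <- diff(log(ks)) / diff(xs)
  expect_equal(slopes, rep(e_p / (cst$k_B * temp), length(slopes)),
               tolerance = 1e-9)
  # boost series is the same scaling applied to a baseline constant
  series <- photon_boost_series(ks[1], e_p, temp, xs)
  expect_equal(series$k_second_order, ks, tolerance = 1e-9)
  # at positive barrier the rate grows with temperature
  kT1 <- tst_rate(1, 1, 1, 0.5, 0, 0, temperature = 280)$value
  kT2 <- tst_rate(1, 1, 1, 0.5, 0, 0, temperature = 320)$value
  expect_gt(kT2, kT1)
})

test_that("exponential overflow is flagged, never silent", {
  k <- tst_rate(1, 1, 1, u_ts_0 = -50, u_fragment_0 = 0, u_atom_0 = 0,
                temperature = 100)
  expect_true(k$overflow)
  expect_identical(k$value, Inf)
  expect_gt(k$exponent_diagnostic, 700)
})

test_that("pseudo-first-order conversion is multiplication by the concentration", {
  expect_equal(pseudo_first_order(1.11e-3, 0.005)$value, 5.55e-6)
  expect_equal(pseudo_first_order(4.90e17, 0.005)$value, 2.45e15)
  expect_identical(pseudo_first_order(123, 0)$value, 0)
  expect_identical(pseudo_first_order(1, 1)$unit, "per_second")
})

test_that("Marcus rate: trivial points and the activationless maximum", {
  expect_identical(marcus_isc_rate(0, 0.5, -0.2)$value, 0)
  cst <- physical_constants()
  lam <- 0.5; temp <- 298.15
  k_top <- marcus_isc_rate(0.01, lam, -lam, temp)
  expect_equal(k_top$exponent_diagnostic, 0)
  expect_equal(k_top$value,
               (0.01^2 / cst$hbar) * sqrt(pi / (lam * cst$k_B * temp)))
  # Gaussian symmetry about dG = -lambda
  for (d in c(0.05, 0.2, 0.4)) {
    expect_equal(marcus_isc_rate(0.01, lam, -lam + d)$value,
                 marcus_isc_rate(0.01, lam, -lam - d)$value, tolerance = 1e-12)
    expect_lt(marcus_isc_rate(0.01, lam, -lam + d)$value, k_top$value)
  }
  expect_error(marcus_isc_rate(0.01, -0.1, 0), "positive")
})

test_that("Marcus rate agrees with the SI-unit oracle, including cm^-1 couplings", {
  set.seed(11)
  for (i in 1:50) {
    v <- stats::runif(1, 1e-4, 0.05)
    lam <- stats::runif(1, 0.05, 1.5)
    dg <- stats::runif(1, -1, 1)
    temp <- stats::runif(1, 150, 500)
    expect_equal(marcus_isc_rate(v, lam, dg, temp)$value,
                 oracle_marcus(v, lam, dg, temp), tolerance = 1e-10)
  }
  v_cm <- 100
  v_eV <- convert_energy(v_cm, "cm_inverse", "eV")
  expect_equal(marcus_isc_rate(v_cm, 0.5, -0.2, coupling_unit = "cm_inverse")$value,
               marcus_isc_rate(v_eV, 0.5, -0.2)$value)
})

test_that("Landau-Zener probability: limits, bounds and monotonicity", {
  expect_identical(landau_zener_probability(0, 1e13, 1)$value, 0)
  # strictly increasing in the coupling below saturation
  vs <- 10^seq(-4, -1.7, length.out = 30)
  ps <- vapply(vs, function(v)
    landau_zener_probability(v, 1e13, 1)$value, numeric(1))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_true(all(diff(ps) > 0))
  # saturates to unity at strong coupling
  expect_equal(landau_zener_probability(1, 1e13, 1)$value, 1, tolerance = 1e-6)
  # inverse-monotone in velocity
  p_slow <- landau_zener_probability(0.01, 1e12, 1)$value
  p_fast <- landau_zener_probability(0.01, 1e14, 1)$value
  expect_gt(p_slow, p_fast)
  expect_error(landau_zener_probability(0.01, 0, 1), "positive")
  expect_error(landau_zener_probability(0.01, 1e13, 0), "positive")
  # double-passage variant accounts for the return pass
  p1 <- landau_zener_probability(0.01, 1e13, 1)$value
  p2 <- landau_zener_probability(0.01, 1e13, 1, passages = "double")$value
  expect_equal(p2, p1 * (2 - p1))
})

test_that("Landau-Zener agrees with the SI-unit oracle on random draws", {
  set.seed(13)
  for (i in 1:50) {
    v <- stats::runif(1, 1e-4, 0.05)
    vel <- 10^stats::runif(1, 11, 15)
    df <- stats::runif(1, 0.2, 8)
    expect_equal(landau_zener_probability(v, vel, df)$value,
                 oracle_landau_zener(v, vel, df), tolerance = 1e-12)
  }
})

test_that("cycle conversion is the complement of repeated survival", {
  expect_equal(cycle_conversion(0.5, 1), 0.5)
  expect_equal(cycle_conversion(0.5, 2), 0.75)
  expect_equal(cycle_conversion(0.2, 1e4), 1, tolerance = 1e-12)
  expect_identical(cycle_conversion(0.7, 0), 0)
  # smallest cycle count reaching 74% conversion at p = 0.5, by enumeration
  n <- which(cycle_conversion(0.5, 0:20) >= 0.74)[1] - 1L
  expect_identical(n, 2L)
  # monotone in both arguments
  expect_true(all(diff(cycle_conversion(0.3, 0:15)) > 0))
  expect_true(all(diff(cycle_conversion(seq(0, 1, 0.1), 3)) >= 0))
})
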