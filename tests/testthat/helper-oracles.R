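# Independent SI-unit (joule/metre/second) oracle implementations of the
# rate expressions, written against the exact SI-defined constants only.
# These deliberately share no code with the package internals, which work
# in eV throughout.

.si <- list(
  kB = 1.380649e-23,          # J/K (exact)
  h = 6.62607015e-34,         # J s (exact)
  hbar = 6.62607015e-34 / (2 * pi),
  eV = 1.602176634e-19,       # J  (exact)
  amu = 1.66053906660e-27,    # kg
  NA_ = 6.02214076e23
)

# Marcus ISC rate, all inputs in eV / K, computation entirely in joules
oracle_marcus <- function(v_soc_eV, lambda_eV, dg_eV, temperature) {
  V <- v_soc_eV * .si$eV
  lam <- lambda_eV * .si$eV
  dg <- dg_eV * .si$eV
  kT <- .si$kB * temperature
  (V^2 / .si$hbar) * sqrt(pi / (lam * kT)) * exp(-(dg + lam)^2 / (4 * lam * kT))
}

# Landau-Zener single-passage hop probability; velocity in angstrom/s and
# slope difference in eV/angstrom converted to SI
oracle_landau_zener <- function(coupling_eV, velocity_A_s, slope_eV_A) {
  V <- coupling_eV * .si$eV
  v <- velocity_A_s * 1e-10                 # m/s
  dF <- slope_eV_A * .si$eV / 1e-10         # J/m
  1 - exp(-2 * pi * V^2 / (.si$hbar * v * dF))
}

# translational partition function per standard-state volume, SI throughout
oracle_translational_q <- function(mass_amu, temperature, conc_mol_L = 1) {
  m <- mass_amu * .si$amu
  vol <- 1 / (.si$NA_ * conc_mol_L * 1000)  # m^3 per molecule
  (2 * pi * m * .si$kB * temperature / .si$h^2)^1.5 * vol
}

# random channel specification used by the recovery suites
random_channel_spec <- function(activated) {
  list(
    asymptote_energy = stats::runif(1, -1, 1),
    well_depth = stats::runif(1, 0.3, 3),
    barrier_height = if (activated) stats::runif(1, 0.1, 0.5) else 0,
    well_position = stats::runif(1, 1.0, 1.3),
    barrier_position = stats::runif(1, 1.7, 2.2),
    morse_a = stats::runif(1, 1.8, 2.6),
    sigma = stats::runif(1, 0.12, 0.2)
  )
}

make_channel_from_spec <- function(spec, noise_sd = 0, seed = 1) {
  make_channel(asymptote_energy = spec$asymptote_energy,
               well_depth = spec$well_depth,
               barrier_height = spec$barrier_height,
               well_position = spec$well_position,
               barrier_position = spec$barrier_position,
               r_min = 0.8, r_max = 4, step = 0.02,
               noise_sd = noise_sd, seed = seed,
               morse_a = spec$morse_a, sigma = spec$sigma)
}
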