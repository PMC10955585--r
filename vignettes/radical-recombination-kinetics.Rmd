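---
title: "Two-step radical reaction energetics and nonadiabatic kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step radical reaction energetics and nonadiabatic kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radikin)
```

## The problem

Thio-substituted nucleobases such as 2-thiocytosine populate long-lived
triplet states in near-unity yield under UVA light, although they contain
only light atoms, for which spin–orbit couplings (1–100 cm⁻¹) make
intersystem crossing (ISC) between singlet and triplet surfaces an
implausibly slow route. An alternative, purely photochemical rationale is a
*two-step radical scheme*: the photon first breaks an X–H bond
homolytically (here the S–H bond of the amino-thiol tautomer), and the
radical pair then recombines. Because the separated pair TC2• + H• is
spin-degenerate, recombination proceeds with equal probability along a
singlet channel (barrierless, regenerating the ground-state tautomer) and
triplet channels (small barriers, falling into bound triplet wells of the
amino-thion tautomers). No spin flip is ever required. The canonical base
cytosine serves as the control: its O–H/N–H homolysis asymptotes lie above
the UVA photon energy, so no triplet route opens and only ultrafast decay
is observed — matching experiment.

`radikin` implements the quantitative machinery of this argument. It never
computes wavefunctions: it consumes tabulated electronic energies and
zero-point energies (ZPE) from multireference calculations, plus 1-D
potential-energy scans, and turns them into relative-energy tables,
feasibility verdicts, channel characterizations and rate constants.

## Species ledgers and feasibility gating

A *species ledger* holds one row per species: electronic energy (hartree),
harmonic ZPE (hartree), spin multiplicity and role. Two reference ledgers
are installed with the package (checksum-verified on load): ZPE-corrected
CASPT2/CASSCF energies for the four lowest singlet tautomers of
2-thiocytosine and its singlet/triplet radical asymptotes, and the
analogous set for cytosine.

```{r ledger}
rel <- relative_energies(make_ledger_fixture("table1"), use_zpe = TRUE)
rel
```

Relative energies are differenced in hartree against the declared reference
(the most stable tautomer) and converted once to eV and kcal/mol, so the
two columns can never drift apart. The near-degenerate singlet and triplet
asymptotes are kept as distinct records, never merged; the tiny splitting
is an artefact of the finite multiconfigurational space that produced the
energies, and averaging it away would hide that provenance.

Feasibility gating compares an asymptote's relative energy against a
radiation band's upper photon energy:

```{r gate}
feasibility_gate(rel$rel_energy_eV[rel$role == "radical_asymptote"],
                 radiation_band("UVA", 3.89))
```

Design choices worth stating:

* **Inclusive boundary.** `asymptote <= max_photon_energy` counts as
  reachable. Real cases sit well away from the edge (3.44 eV vs 3.89 eV,
  margin ≈ 0.45 eV); equality is a degenerate case we define rather than
  leave undefined.
* **The band edge is configuration, not physics.** With the CODATA value
  of hc, 321 nm corresponds to 3.862 eV and 308 nm to 4.025 eV, while the
  customary literature figures for these band edges are 3.89 and 4.05 eV.
  `wavelength_to_photon_energy()` always reports the computed hc/λ and the
  package never silently substitutes the rounded literature figures; the
  default UVA edge of 3.89 eV in examples is a user-visible configuration
  value chosen to match common usage, and both conventions lead to
  identical verdicts here.
* **Display rounding only.** Tables print eV to 2 decimals and kcal/mol to
  1 decimal (the conventional precision for this kind of tabulation), but
  all stored columns keep full double precision. Note that reference
  tabulations of this kind often carry rounded intermediates, so a
  recomputed value can legitimately differ from a printed one by one unit
  in the last digit.

## Potential-curve characterization

Scans are 1-D curves of energy (eV) against the H-to-attacked-atom distance
(Å); increasing coordinate means separating fragments, so recombination is
read right to left. The analysis is deliberately low-order and transparent:

* **Stationary points**: interior sign changes of the finite-difference
  slope, refined by a quadratic through the three bracketing points
  (exact for locally parabolic curves; the refined vertex is rejected and
  the raw grid point kept if it falls outside its bracket, which guards
  against noise-driven extrapolation). Endpoints are never stationary.
* **Channel classification**: with the asymptote taken from the last grid
  point (or supplied explicitly), a channel is *activated* when some
  interior maximum exceeds the asymptote by more than a tolerance
  (default 0.005 eV — about the size of wiggle a converged scan can carry
  without implying a real barrier), *barrierless* otherwise, and
  *repulsive* when the curve never dips below the asymptote but rises
  above it at short range. Barrier height and well depth are measured
  from the asymptote.
* **Crossings**: both curves are linearly re-interpolated onto their
  common-span union grid; each sign change of the energy difference is
  localized by linear interpolation and slopes are estimated by central
  differences. Zeros without a sign change (touching) are excluded, and
  results are sorted by energy so the first row is the lowest-lying
  crossing — the one that matters for ISC estimates. Linear interpolation
  was chosen over splines because its error model is trivial (first-order
  convergence verified in the tests); spline refinement would buy little
  at the 0.02 Å grids used here.

## The synthetic generator

The multireference scans behind the published figures are not tabulated
anywhere, so the package carries a generator that emulates their shapes
with known ground truth: a Morse well (depth and position of the product
well) plus a Gaussian bump (barrier guarding the well at larger
separation). Because the two terms overlap, requested depths/heights would
be distorted by up to a few tenths of an eV if the amplitudes were used
naively; a fixed-point calibration loop instead adjusts both amplitudes
until the *composite* curve's extrema match the request to better than
1 µeV, and the calibrated extremum locations are reported as truth.
Point-wise Gaussian noise is added under an explicit seed (default
20240308) without touching the caller's RNG stream, and the truth record
is seed-independent.

What the generator does and does not emulate: it reproduces the
geometric features that the scan analysis must recover — asymptote, well,
barrier, smoothness, optionally point noise — but not state mixing,
multi-state degeneracies or the coordinate-dependent character of real
CASPT2 wavefunctions. Passing the recovery suites therefore demonstrates
that the *analysis* is correct, not that any particular electronic
structure is.

Default study conditions used by the test and acceptance suites: grids of
0.8–4.0 Å at 0.02 Å steps, wells of 0.3–3 eV, barriers of 0.1–0.5 eV
(bracketing the 0.29–0.4 eV range characteristic of these triplet
channels), Morse range parameters 1.8–2.6 Å⁻¹ and bump widths
0.12–0.2 Å; 200 randomized channels and 500 randomized crossing pairs,
sizes chosen so the whole suite runs in seconds while still giving stable
recovery fractions. Recovery is asserted to 0.01 eV (noise-free) and to
0.02 eV for ≥95 % of channels at 0.005 eV point noise.

```{r synth}
ch <- make_channel(well_depth = 0.9, barrier_height = 0.4, noise_sd = 0)
characterize_channel(ch$curve, asymptote_energy = 0)
```

## Kinetics

Three closed-form rate expressions, all evaluated internally in eV and
seconds (constants pinned to CODATA 2018; the eV-scale constants are
derived from the exact SI ones so that eV-unit and SI-unit evaluations of
the same formula agree to machine precision):

**Canonical TST with photon-energy partitioning.** For the bimolecular
recombination of the heavy radical with H•,
$$k = \frac{k_B T}{h}\frac{Q^{TS}}{Q_{frag}\,Q_{H}}
 \exp\!\left(-\frac{U^{TS}_0-U^{frag}_0-U^{H}_0-x\,e_p}{k_B T}\right),$$
where a fraction $x$ of the photon energy $e_p$ resides in the H atom and
lowers the effective barrier. The complementary fraction absorbed by the
heavy fragment is assumed to redistribute over its many modes and persist
into the transition state, leaving the partition-function ratio — and
hence the rate — unchanged. Partition functions are RRHO
(`rrho_partition_functions()`), translational factors per 1 mol/L standard
state so the rate lands directly in M⁻¹ s⁻¹. The default temperature is
298.15 K; the reference rate table this reproduces never states its
temperature, and 298.15 K is both the universal thermochemistry default
and consistent with that table's x-scaling to within ~1 %.
`photon_boost_series()` applies the same scaling to a baseline constant
and appends the pseudo-first-order column (× concentration, default
0.005 M).

**Marcus ISC rate.**
$$k_{ISC} = \frac{V_{SOC}^2}{\hbar}\sqrt{\frac{\pi}{\lambda k_B T}}
 \exp\!\left(-\frac{(\Delta G_{ST}^{v}+\lambda)^2}{4\lambda k_B T}\right),$$
maximal at $\Delta G = -\lambda$ and quadratic in the coupling — which is
exactly why ISC through a crossing is implausible for light-atom systems
with $V_{SOC} \lesssim 100$ cm⁻¹. Couplings are accepted in cm⁻¹ or eV
with an explicit unit key.

**Landau–Zener hopping.** Single-passage probability
$P = 1-\exp(-2\pi V^2/(\hbar v\,|\Delta F|))$, taking the slope difference
straight from a located crossing. Single passage is the default because
it is the textbook form and published single numbers rarely state the
variant; a `passages = "double"` flag gives $P(2-P)$, the probability of
hopping on either pass of one traversal cycle. The adiabatic limit
(vanishing velocity or slope difference) is rejected rather than
extrapolated.

**Cycle conversion.** Since singlet-channel recombination returns
population to the absorbing ground state, repeated excitation–decay
cycles convert the remainder: fraction $1-(1-p)^n$ after $n$ cycles. With
equal singlet/triplet branching ($p = 0.5$), two cycles already exceed
the ~74 % conversion observed on the picosecond scale for 2-thiocytosine.

Numerical policies: exponents beyond 700 in natural-log space return a
flagged `Inf` (with the exponent preserved in `exponent_diagnostic`)
rather than wrapping; probabilities are validated into [0, 1]; none of
the kinetics operations is stochastic, so no seeds are involved there.

## Validation strategy and limitations

The published scan-derived numbers (barriers of 0.29/0.4/0.31 eV, wells at
2.83/2.91 eV, an ISC rate of 3.33 × 10¹² s⁻¹, a hopping probability of
0.1072) cannot be recomputed here because their inputs — the CASPT2
curves and the crossing-point parameters — are not tabulated in any
available source. The package therefore validates:

* table reproduction: both shipped ledgers reproduce every eV and
  kcal/mol entry of their source tabulations within one unit of the last
  printed digit;
* internal consistency: the electronic-energy (non-ZPE) triplet asymptote
  minus the reported well energies recovers the reported 0.9/0.82 eV well
  depths to better than 0.015 eV;
* rate-table reproduction: the photon-boost series reproduces the
  reference second-order column within 3 % (1 % at x = 0.10) and the
  pseudo-first-order column at printed precision;
* property-based recovery: generator ground truth on randomized synthetic
  channels and crossing pairs, and agreement of the Marcus/Landau–Zener
  implementations with independent SI-unit oracle evaluations to
  10⁻¹⁰ relative on 1000 random draws.

Out of scope by design: electronic-structure computation of any kind,
multi-dimensional surfaces, conical-intersection optimization,
vibronically resolved ISC theories, RRKM/microcanonical rates, solvent
models and thermal corrections beyond ZPE.
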