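# radikin

Energetics and nonadiabatic kinetics for **two-step radical reaction
schemes** in nucleobase photochemistry.

Thiobases such as 2-thiocytosine reach long-lived triplet states in
near-unity yield under UVA light even though their spin–orbit couplings
(1–100 cm⁻¹, light atoms only) make direct intersystem crossing slow. A
photochemical alternative explains this without any spin flip: the photon
homolytically cleaves an X–H bond (for 2-thiocytosine, the S–H bond of the
amino-thiol tautomer), and the spin-degenerate radical pair then recombines
with equal probability along a barrierless singlet channel (back to the
ground-state tautomer) and along triplet channels that fall into bound
amino-thion wells. For cytosine, the control case, the homolysis asymptotes
lie above the UVA photon energy, so the radical route never opens — and no
triplets are observed.

`radikin` is for computational photochemists who have the energies (from
multireference calculations) and want the analysis: it consumes species
energy ledgers and 1-D potential scans and produces relative-energy tables,
photon-feasibility verdicts, channel characterizations (wells, barriers,
singlet–triplet crossings) and rate constants.

The core quantitative pieces:

* **Canonical TST with photon-energy partitioning** — a fraction *x* of the
  photon energy *e*ₚ resides in the attacking H atom and lowers the
  effective recombination barrier:
  *k* = (*k*_B*T*/*h*) · (*Q*^TS/*Q*_frag *Q*_H) · exp(−(*U*₀^TS − *U*₀^frag − *U*₀^H − *x e*ₚ)/*k*_B*T*)
* **Semiclassical Marcus ISC rate** —
  *k*_ISC = (*V*²_SOC/ħ) √(π/λ*k*_B*T*) · exp(−(Δ*G*^v_ST + λ)²/4λ*k*_B*T*)
* **Landau–Zener hopping probability** —
  *P* = 1 − exp(−2π*V*²/(ħ*v*|Δ*F*|)), slopes taken from a located crossing
* **Seeded synthetic scan generator** (Morse well + calibrated Gaussian
  barrier) with analytic ground truth, validating the scan analysis.

## Worked example

```r
library(radikin)

rel <- relative_energies(make_ledger_fixture("table1"))  # 2-thiocytosine
rel
#> Relative energies (reference 'TC2', ZPE-corrected)
#>        label multiplicity              role   eV kcal_mol
#>          TC2      singlet          tautomer 0.00      0.0
#>          TC1      singlet          tautomer 0.23      5.3
#>          TC4      singlet          tautomer 0.28      6.5
#>          TC3      singlet          tautomer 0.53     12.3
#>     (S)TC2+H      singlet radical_asymptote 3.44     79.2
#>     (T)TC2+H      triplet radical_asymptote 3.46     79.7
#>  (S)TC1_NH+H      singlet radical_asymptote 4.21     97.0
#>  (T)TC1_NH+H      triplet radical_asymptote 4.23     97.5
```

The S–H homolysis asymptotes sit at 3.44/3.46 eV — below a 3.89 eV UVA
photon — while H abstraction from the amino group (4.21/4.23 eV) is out of
reach:

```r
feasibility_gate(rel$rel_energy_eV[rel$role == "radical_asymptote"],
                 radiation_band("UVA", 3.89))
#>   asymptote_eV band     verdict  margin_eV
#> 1     3.436172  UVA   reachable  0.4538278
#> 2     3.456472  UVA   reachable  0.4335281
#> 3     4.206581  UVA unreachable -0.3165810
#> 4     4.226228  UVA unreachable -0.3362276
```

So UVA can make the radicals. How fast do they recombine through a triplet
channel? Even a modest share of the photon energy in the H atom accelerates
the reaction by many orders of magnitude:

```r
photon_boost_series(1.11e-3, e_p = 3.49, fractions = c(0, 0.1, 0.35))
#>      x k_second_order k_pseudo_first_order
#> 1 0.00   1.110000e-03         5.550000e-06
#> 2 0.10   8.803271e+02         4.401636e+00
#> 3 0.35   4.931134e+17         2.465567e+15
```

At x = 0.35 the pseudo-first-order constant (at 0.005 M) reaches
2.5 × 10¹⁵ s⁻¹ — femtosecond-scale, consistent with the observed ultrafast
triplet population. Finally, the scan machinery recovering a known channel
shape (a 0.9 eV well guarded by a 0.4 eV barrier, the profile of the
deepest triplet channel):

```r
ch <- make_channel(well_depth = 0.9, barrier_height = 0.4, noise_sd = 0)
characterize_channel(ch$curve, asymptote_energy = 0)
#> Channel synthetic (triplet): activated
#>   barrier height: 0.4000 eV above asymptote
#>   well depth:     0.9000 eV below asymptote
#>   asymptote:      0.0000 eV
```

See the vignette (`vignettes/radical-recombination-kinetics.Rmd`) for the
models, assumptions and numerical choices, and `inst/cli/radikin.R` for the
command-line interface (`constants`, `ledger`, `scan`, `synth`, `kinetics`,
`run`).

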