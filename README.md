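# chex2dir

Tools for quantifying how a water molecule weakly bound to a peptide
backbone carbonyl exchanges with the fully hydrated state, from infrared
spectroscopy. The model system is a single-amide β-peptide fragment in
water whose amide-I band splits into two overlapping sub-bands: a
low-frequency component from carbonyls with two strong water hydrogen bonds
(the SHB state) and a high-frequency component from carbonyls with one
strong and one weak/absent hydrogen bond (the WHB state). The package
implements the complete analysis chain for this two-state picture and a
synthetic-data generator that stands in for the spectrometer and for a
molecular-dynamics engine, so every stage is testable end to end.

## The analysis

**FTIR decomposition.** A Savitzky–Golay second derivative locates the two
sub-bands; the band is fitted as two Voigt profiles (evaluated through the
Faddeeva function `w(z)`) plus a baseline, giving per-temperature centers
and integrated areas. The SHB center drifts linearly with temperature
(≈ 0.07 cm⁻¹/°C).

**Thermodynamics.** Because the integrated absorption of each sub-band is
proportional to concentration times squared transition dipole,

```
K_eq = C_WHB / C_SHB = (A_WHB · μ_SHB²) / (A_SHB · μ_WHB²)
```

and an unweighted van't Hoff regression `ln K_eq = −ΔH/(RT) + ΔS/R` yields
the enthalpy and entropy of the SHB → WHB transition, with
`ΔG(T) = ΔH − TΔS`. A sensitivity analysis rescales `K_eq` for alternative
WHB dipoles (ΔH is invariant; ΔS shifts by exactly `R ln f`).

**Chemical-exchange 2D IR kinetics.** Each waiting-time (`T_w`) spectrum is
normalized by the integrated magnitude of the SHB 1→2 diagonal peak
(removing population and orientational relaxation), the `T_w = 0` spectrum
is subtracted, and the SHB→WHB cross-peak window (~25 cm⁻²) is integrated.
The growth is fitted as `A·(1 − exp(−T_w/τ))`, giving the forward rate
`k₁ = 1/τ`; detailed balance `k₁ = k₋₁·exp(−ΔG/RT)` gives the reverse
rate, and Arrhenius fits of `ln k` vs `1/T` give the activation energies.

**Hydration-shell statistics.** For labeled XYZ trajectories: radial
distribution functions, shell coordination numbers, geometric hydrogen-bond
counts (donor–acceptor distance < 3.5 Å, deviation angle < 40°), the two
nearest carbonyl-O···water-H distances per frame, and SHB/WHB frame
classification by the second-nearest distance (cutoff 2.55 Å, the first
RDF minimum).

## Worked example

```r
library(chex2dir)
res <- run_pipeline()          # simulate -> fit -> van't Hoff -> 2D IR -> Arrhenius
res$report
```

prints (seed 1, default study conditions):

```
dH = 6.22 +/- 0.00 kJ/mol
dS = 15.34 +/- 0.00 J/mol/K
SHB drift = 0.0700 cm-1/degC
  temperature_c tau_forward_ps k1_ps1 tau_reverse_ps k_reverse_ps1 dG_used_kJmol
1            23         0.5300 1.8869         0.2682        3.7286        1.6771
2            50         0.3299 3.0316         0.2062        4.8507        1.2629
3            60         0.2798 3.5738         0.1875        5.3344        1.1095
4            85         0.2091 4.7830         0.1638        6.1035        0.7260
Ea(forward) = 13.32 +/- 0.49 kJ/mol
Ea(reverse) = 7.10 +/- 0.49 kJ/mol
```

Reading: the refitted synthetic FTIR series returns the generating
thermodynamics exactly (ΔH = 6.22 kJ/mol, ΔS = 15.34 J/mol/K, hence
ΔG(23 °C) = 1.68 kJ/mol); the 2D IR extraction recovers the forward
exchange time constants (0.53 ps at 23 °C, i.e. the weak hydrogen bond
breaks in about half a picosecond at room temperature, faster when hot);
detailed balance makes the reverse exchange faster still (0.27 ps at
23 °C); and the Arrhenius fits put the forward barrier near 13.3 kJ/mol
and the reverse barrier near 7.1 kJ/mol (their difference is ΔH, as it
must be).

Individual stages are plain functions — `simulate_ftir()`,
`fit_two_voigt()`, `thermo_from_areas()`, `simulate_2dir_series()`,
`exchange_protocol()`, `arrhenius_fit()`, `reverse_rate()`, `rdf()`,
`hbond_count()` — see the vignette source in `vignettes/` for the model,
its assumptions, and every tunable parameter.

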