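---
title: "Two-state amide-water hydrogen-bond exchange: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state amide-water hydrogen-bond exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chex2dir)
```

## The physical picture

A peptide backbone carbonyl in water can hold at most two hydrogen-bonded
water molecules. The package models the resulting heterogeneity as a
two-state equilibrium: an SHB state (two strong C=O···H–O bonds) absorbing
at the low-frequency side of the amide-I band, and a WHB state (one strong
bond plus one weak or broken second bond) absorbing ~13 cm⁻¹ higher.
Everything the package computes follows from this two-state assumption:

* the amide-I band is a sum of exactly two Voigt components;
* their area ratio, corrected for the squared transition-dipole ratio,
  is the equilibrium constant `K_eq(T)`, whose van't Hoff regression gives
  ΔH and ΔS of the SHB → WHB transition;
* interconversion during the waiting time of a 2D IR experiment produces
  cross peaks whose growth encodes the forward rate `k₁`, with the reverse
  rate fixed by detailed balance `k₁ = k₋₁ e^{−ΔG/RT}`;
* in a molecular trajectory the same two states appear as a bimodal
  second-nearest carbonyl-O···water-H distance, classified with a shell
  cutoff.

All molar energies use the gas constant `R = 8.314462618 J mol⁻¹ K⁻¹`;
temperatures convert as `K = °C + 273.15`. Using the molar convention (not
per-molecule k_B with molar ΔG) is what makes a 0.53 ps forward time
constant and ΔG = 1.68 kJ/mol at 296.15 K yield a 0.27 ps reverse time
constant; a unit test pins this.

```{r detailed-balance}
1 / reverse_rate(1 / 0.53, dG = 1.68, temperature_k = celsius_to_kelvin(23))
```

## FTIR decomposition

`second_derivative()` is a Savitzky–Golay local-polynomial filter
(default 11-point window, cubic, matched to 1 cm⁻¹ sampling). Two caveats
are worth knowing. First, endpoints use the filter's asymmetric boundary
kernels and are flagged in the metadata. Second, smoothing attenuates
curvature: with the default window the second-derivative *amplitude* of a
5 cm⁻¹-wide Gaussian is ~20% low, while minima *positions* — the only
thing the pipeline consumes — stay put to a fraction of the grid spacing.
Callers who need quantitative second derivatives should shrink the window
or raise the order (7-point quintic is accurate to ~0.2%).

`fit_two_voigt()` does bounded Levenberg–Marquardt least squares on two
Voigt profiles plus a constant (optionally linear) baseline. The Voigt is
evaluated through the real part of the Faddeeva function, computed with
Weideman's 48-term rational approximation and a Laplace continued fraction
in the far wings (validated to ~1e−15 relative error against a
multiple-precision reference); a pure pseudo-Voigt approximation is
deliberately *not* used. Centers are bounded to ±10 cm⁻¹ of their starting
values and widths to (0.1, 30) cm⁻¹, which prevents the two components
from trading places on hard problems; components are always reported
sorted by center (SHB below WHB). Initialization is automatic from the two
deepest second-derivative minima; with fewer than two minima the fit
refuses to guess and asks for an explicit `init`. A residual RMS above 2%
of the band maximum warns but does not fail.

## Thermodynamics

`equilibrium_constant()` implements
`K_eq = (A_WHB μ_SHB²)/(A_SHB μ_WHB²)` with the gas-phase dipoles
0.344/0.321 D as defaults. `vant_hoff_fit()` is an *unweighted* ordinary
least-squares fit of `ln K_eq` on `1/T`; reported standard errors are
regression errors only and are labeled as such (they do not propagate the
per-area fit uncertainties). `dipole_sensitivity()` exploits the exact
algebra of the model: a temperature-independent rescaling of `K_eq` by `f`
leaves ΔH untouched and shifts ΔS by `R ln f`, so the WHB-dipole
uncertainty maps cleanly onto an entropy band. The in-text dipole-ratio
label sometimes quoted as "1.32:1" is treated as the *squared* ratio
(0.344²/0.304² = 1.28 ≈ 1.3); the entropy endpoints 14.20 and
16.25 J mol⁻¹ K⁻¹ are what arbitrate, and both are reproduced exactly by
the `R ln f` shift.

A reporting-precision subtlety: the reverse-rate Arrhenius energy is
sensitive to rounding of the sub-picosecond reverse time constants.
Computing `k₋₁(T)` from the printed `k₁` and ΔG values and fitting
Arrhenius on the *unrounded* rates gives `Ea(rev) = Ea(fwd) − ΔH ≈ 7.0
kJ/mol` (the detailed-balance identity), while fitting the same rates
rounded to the conventional 0.01 ps reporting precision gives ≈ 7.5
kJ/mol. The acceptance suite checks the rounded-precision route because
that is what the benchmark values encode; both numbers are computed by the
package, nothing is assumed.

## The 2D IR generator and the extraction protocol

Each waiting-time spectrum is a sum of separable 2D Gaussian peak pairs:
for every population pathway i → j a positive peak at
(ω_i(0→1), ω_j(0→1)) and a negative peak shifted down the probe axis by
the anharmonicity Δ_anh (default 13 cm⁻¹, set by the observed gap between
the SHB fundamental and the 1→2 probe window). Peak amplitude is
(initial population of i) × (pathway weight) × (lifetime damping). Two
kinetic constructions are provided:

* **phenomenological** (default): diagonal weights stay 1 and cross
  weights grow as `1 − exp(−T_w/τ)`. This is the construction under which
  the field's standard protocol — normalize by the SHB 1→2 diagonal
  window, subtract `T_w = 0`, integrate the cross window, fit a single
  exponential — returns *exactly* `1/τ_forward`. It encodes the
  convention that assigns the fitted single-exponential growth rate to the
  forward rate constant.
* **master_equation**: pathway weights are the conditional probabilities
  `exp(K T_w)` of the two-state rate matrix (closed form via the
  relaxation eigenvalue `k_f + k_r`). Under this rigorous kinetics the
  cross-peak growth eigenvalue is `k_f + k_r`, not `k_f`, so the same
  protocol returns the faster relaxation rate. The two modes therefore
  *disagree by design*; the package documents rather than hides this
  divergence, and the phenomenological mode is the default because it is
  the construction consistent with the single-exponential assignment.

Lifetime damping defaults to the *initially pumped* state's `T₁`
(`lifetime_convention = "initial"`), because then all pathways sharing a
pump state decay together and the normalization window — itself a pumped-
SHB pathway — cancels population relaxation exactly, which is the stated
purpose of the normalization step. The `"final"`-state convention is
selectable; in sub-picosecond exchange the truth lies between the two, and
the protocol's normalization makes the choice nearly immaterial (a unit
test verifies the fitted τ moves < 2% under large `T₁` changes).

Free parameters the underlying experiment does not pin down, chosen once
and documented here rather than presented as measured values:

* 2D Gaussian linewidths σ = 2.75 cm⁻¹ (FWHM ≈ 6.5 cm⁻¹), a homogeneous
  width consistent with ~1 ps total dephasing;
* waiting-time grid 0–3 ps in 0.1 ps steps;
* vibrational lifetimes 0.67 / 0.72 ps (SHB/WHB) as generator defaults;
* window geometry: 5 × 5 cm⁻¹ (≈ 25 cm⁻²) squares, normalization on the
  SHB 1→2 diagonal peak, cross window at (pump = SHB 0→1,
  probe = WHB 0→1); windows follow the drifted centers at each
  temperature. Integrals are signed; normalization uses the absolute
  magnitude.

Because the WHB 1→2 probe frequency sits within ~0.1 cm⁻¹ of the SHB
fundamental when the split (13.1 cm⁻¹) nearly equals Δ_anh (13 cm⁻¹), the
exchange cross peaks deliberately overlap the diagonal 1→2 peaks — the
generator makes no attempt to separate what the experiment cannot.

## The FTIR generator

Component centers drift linearly (defaults +0.07 cm⁻¹/°C for SHB,
+0.02 cm⁻¹/°C for WHB — the low-frequency band shifts clearly, the
high-frequency band only slightly), total band area falls by 0.2%/°C
(extinction loss), and the area ratio follows `K_eq(T)` from the default
ΔH = 6.22 kJ/mol, ΔS = 15.34 J mol⁻¹ K⁻¹. Component widths default to
σ_G = 3.8, γ_L = 1.3 cm⁻¹ (Voigt FWHM ≈ 10.4 cm⁻¹). This is narrower than
the apparent amide-I width because the *envelope* of two such components
13 cm⁻¹ apart is ~20 cm⁻¹ wide, and because second-derivative resolvability
constrains the components: with a 2.26:1 amplitude ratio, two minima
within 1 cm⁻¹ of the true centers exist only for component FWHM ≲ 12 cm⁻¹.
Broader components would make the generator's own doublet undetectable by
the detection stage that the experiment demonstrably performs.

## Toy hydration trajectories

`simulate_trajectory()` builds one amide fragment plus waters in a cubic
periodic box (defaults 28 Å). Three designs target specific statistics:
`uniform` is an ideal-gas reference (g(r) → 1); `designed_shell` places a
constructed number of donated hydrogens at 1.65 ± 0.08 Å so the shell
coordination number is known exactly; `telegraph_hbond` switches a tagged
second water between bound (1.85 Å) and unbound (3.0 Å) distances by a
two-state telegraph process with stationary bound fraction
`on/(on + off)`. What these toys do *not* emulate: excluded volume beyond
a 0.5 Å overlap rule, water structure (no O–O correlation hole), forces,
or dynamics within a state. Passing tests therefore validate the
*analysis operators* (histogramming, minimum-image convention, bond
geometry, classification) — they say nothing about force-field realism,
and the literature values that depend on a real force field (2.06 shell
hydrogens, 1.39 mean hydrogen bonds, RDF extrema at 1.65/2.55 Å) are used
only as construction targets for the toys, never asserted as physics.

The hydrogen-bond angle criterion "donor–proton–acceptor angle < 40°" is
geometrically ambiguous as written — at the proton, a near-linear bond has
an angle near 180°, which a literal "< 40°" would *exclude*. The default
(`angle = "deviation"`) uses the angle between the D→H and D→A vectors,
the common practice that keeps near-linear bonds; the literal at-proton
reading is selectable (`angle = "at_proton"`) for comparison.

Minimum-image distances support orthorhombic (cubic) boxes only;
non-periodic trajectories are handled by omitting the box. Hydrogens are
assigned to their donor heavy atom by proximity (< 1.25 Å), so H and D
are interchangeable labels.

## Numerical choices and degenerate inputs

* Voigt limits: γ = 0 and σ = 0 use the exact Gaussian and Lorentzian
  closed forms; σ = γ = 0 is an error (a delta function is not a band).
* `exchange_populations()` with both rates 0 returns the identity; columns
  sum to 1 to 1e−12 for all inputs by construction.
* `fit_exchange()` rejects fits whose τ lands on its bounds
  ([1e−3, 1e3] ps) or below half the waiting-time spacing (a constant
  trace looks like a step; the rate is unidentifiable and is reported as
  an error with diagnostics, never silently returned).
* `normalize_series()` errors, naming the waiting time, if a window
  integral falls below 1e−12 of the matrix maximum.
* Coordination numbers integrate `ρ g(r) 4πr²` by trapezoid with the last
  partial shell closed at `r_cut`, which keeps wide-bin integrals within a
  fraction of a percent of direct counts.
* RDF normalization uses exact shell volumes `(4π/3)(r³_hi − r³_lo)`
  rather than `4πr²Δr`.
* All generators restore the caller's RNG state; identical parameters and
  seed give bit-identical output.

## Problem sizes

The test suite and the pipeline were sized for quick, fully deterministic
runs: FTIR series of 7 temperatures on a 151-point grid; 2D series of 31
waiting times on 211 × 211 grids at four temperatures; ideal-gas RDF
statistics from 1000 frames × 500 waters; telegraph classification from
3000 frames. These sizes put the counting noise of the stochastic checks
well inside their 3σ assertions while the whole suite runs in well under a
minute.

## Known limitations

* Exactly two components; no Fermi-resonance or multi-state extensions.
* No full third-order response: 2D line shapes are separable Gaussians
  without diagonal elongation, so center-line-slope or nodal-line
  spectral-diffusion analyses are out of scope (window integrals are
  insensitive to them by design).
* Uncertainties are regression-only unless stated; the ΔG error band
  propagates ΔH/ΔS errors (with covariance) but not sub-band area errors.
* Text XYZ only; no binary trajectory formats.
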