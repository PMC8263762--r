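---
title: "Methods and design notes for lakegas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for lakegas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakegas)
```

This vignette explains the models implemented in `lakegas`, their
assumptions, the defaults and where they come from, what the synthetic
generator does and does not emulate, and the numerical and design
choices made where the literature leaves them open.

## The setting

The package targets meromictic soda lakes: alkaline (pH > 9),
carbonate-dominated, permanently stratified water bodies. Two interfaces
organise everything: the *oxycline* (dissolved O₂ collapse, here near
1.5 m) splitting oxic from anoxic surface waters (OSW/ASW), and the
*chemocline* (abrupt conductivity and solute change, here near 3.5 m)
isolating the bottom waters (BW, the monimolimnion). Dissolved CH₄ can
reach hundreds of µmol L⁻¹ even in the oxic surface layer, while the
high-pH carbonate system keeps free CO₂ so scarce that the lake absorbs
atmospheric CO₂ while degassing CH₄.

## Water–air fluxes

The thin-boundary-layer model treats the flux of gas *i* as transfer
velocity times air–water disequilibrium, `Φᵢ = β kᵢ (Cᵢ,w − Cᵢ,eq)`.
Assumptions: a quasi-steady diffusive sublayer, a well-mixed surface
from which `Cᵢ,w` is taken (the 0.5 m sample in practice), and
equilibrium solubility at the interface.

Pieces and defaults:

* **Schmidt numbers** (`schmidt_number()`): fourth-order freshwater
  polynomial fits in temperature (Wanninkhof), valid 0–40 °C; outside
  that range the function errors (configurable to warn). Salinity
  corrections to Sc are not applied; the mixolimnion salinity of the
  target systems is low and unreported.
* **k600 registry** (`k600_model()`): `0.72·U10`
  (Crusius–Wanninkhof), `0.215·U10^1.7 + 2.07` (Cole–Caraco),
  `0.23·U10² + 0.1·U10` (Nightingale). Units cm h⁻¹, U10 in m s⁻¹. All
  three are reported side by side rather than picking one: on sheltered
  crater lakes the wind-based relations bracket the plausible range.
* **Schmidt scaling** (`transfer_velocity()`): exponent −0.67 for
  U10 < 3 m s⁻¹ (smooth surface), −0.5 otherwise. The boundary value
  3 m s⁻¹ itself is assigned to the rough regime, for continuity as wind
  increases; published statements cover only "<3" and ">3".
* **Equilibrium concentration** (`equilibrium_concentration()`):
  solubility × dry mole fraction × station pressure. Solubilities are
  Weiss (1974) K₀ for CO₂ and the Wiesenburg–Guinasso (1979) Bunsen fit
  for CH₄ (O₂: Weiss 1970). Station pressure uses the isothermal
  barometric formula `exp(−z/8400 m)`; at 1884 m elevation that is
  0.799 atm. Defaults for the atmosphere are 410 ppm CO₂ and 1.87 ppm
  CH₄ (modern values; configurable). The *dry-pressure convention* is
  used (no water-vapour subtraction). Each of these conventions moves
  the CO₂ equilibrium concentration, and hence the CO₂ invasion flux, by
  a few percent; CH₄ is insensitive because its equilibrium
  concentration (~0.002 µmol L⁻¹) is negligible against observed
  surface concentrations.
* **Unit chain** (`diffusive_flux()`): cm h⁻¹ × 0.24 → m d⁻¹;
  µmol L⁻¹ ≡ mmol m⁻³; × 12.011 mg C mmol⁻¹. Positive flux = evasion.

### Chemical enhancement of CO₂

At pH ≥ 9.5 a CO₂ molecule entering the boundary layer is likely to
react (hydration, and dominantly hydroxylation by OH⁻) before it mixes,
which steepens its gradient and multiplies the invasion flux by the
Hoover–Berkshire factor β (`enhancement_factor()`). The rate constants
default to temperature-dependent literature fits (Johnson 1982 for the
hydration rate `r1`; a `log10 kOH = 13.635 − 2895/T` fit for the
hydroxylation rate `r2`), and the CO₂ diffusivity uses the Zeebe
power-law fit. All are overridable.

Two properties anchor the implementation and are enforced by tests:
β ≥ 1 everywhere, and β → 1 as k → ∞. In the strongly enhanced regime
βk → √(rτD), so the enhanced flux becomes *independent of wind*: the
three k600 models then give nearly identical CO₂ uptake (≈ −211
mg C m⁻² d⁻¹ under the worked-example conditions). Published flux
tables for such lakes instead scale linearly with k600, which is only
consistent with β = 1. `flux_table()` therefore reports **both
pathways** — `flux_mgC_m2_d` at β = 1 and `flux_enhanced_mgC_m2_d`
with the film-reaction β — rather than guessing which the reader wants;
the β = 1 column is the one comparable to the published tables, while
the enhanced column is the model's own prediction.

## Carbonate system and δ¹³C of CO₂

`d13c_co2_from_tdic()` assumes chemical *and isotopic* equilibrium
among CO₂(aq), HCO₃⁻ and CO₃²⁻ and removes the speciation-weighted
enrichment from the measured δ¹³C-TDIC. Enrichment factors are the
standard linear-in-1/T fits (`9866/T − 24.12` and `1.85 − 666/T` ‰).
Inputs may be given in mmol L⁻¹ or mg L⁻¹ (molar masses 61.017 and
60.009 g mol⁻¹). The computation is exactly linear in δ¹³C-TDIC with
unit slope; the species fractions carry all the temperature dependence.

`speciate_carbonate()` provides closed-form speciation from
`aH = 10^−pH` and the freshwater dissociation constants (Harned–Davis
K₁, Harned–Scholes K₂, Harned–Owen K_w), anchored by TDIC, the measured
(HCO₃, CO₃) pair, or total alkalinity. **No ionic-strength correction
is applied.** This is a documented limitation: in a hypersaline
monimolimnion the effective constants shift (freshwater pK₂ at 21 °C is
≈ 10.37, while the pH implied by measured HCO₃/CO₃ ratios in such
brines is reproduced better with lower effective pK₂), so speciation
from pH alone should be treated as approximate below the chemocline.
The isotope mass balance itself is unaffected when measured
concentrations are supplied directly, which is the recommended use. A
full brine activity model (ion pairing, Pitzer terms) is out of scope.

## Headspace partitioning

`partition_flask()` assumes headspace–liquid equilibrium at analysis
conditions, ideal-gas headspace (R = 0.0820574 L atm mol⁻¹ K⁻¹), and a
linear Henry's law `c_aq = K_H x P`. Flask pressure defaults to 1 atm
at analysis time — field procedures rarely record it — and the default
Henry constants (Sander 2015 compilation at 25 °C) are a replaceable
table; a temperature mismatch beyond a tolerance (default 5 °C) is
recorded as a provenance warning rather than an error. The equivalent
partial pressure is recomputed from total moles over the full flask
volume; this reference-volume convention is arbitrary but documented
and self-consistent. Mass balance `n_t = n_l + n_g` holds to machine
precision by construction and is property-tested.

## Profile diagnostics

* **Chemocline**: midpoint of the interval with maximum
  |Δconductivity/Δz|, ties broken toward the surface (the field
  literature names the feature but no estimator; the maximum-gradient
  midpoint is the simplest consistent choice on coarse sampling grids).
  The estimator is invariant under adding a constant to conductivity
  and equivariant under depth translation.
* **Oxycline**: shallowest midpoint where O₂ crosses below the anoxia
  threshold, default 0.5 mg L⁻¹ (anoxic layers in the target systems
  sit near 0.1 mg L⁻¹; no standard cutoff exists, so it is
  configurable). If O₂ never crosses, the oxycline collapses onto the
  chemocline (no ASW layer) and is flagged; an oxycline estimated below
  the chemocline is clamped with a warning.
* **Depletion depth** (`depletion_depth()`): ordinary least squares of
  concentration on depth over a caller-chosen window, extrapolated to
  zero. The window is deliberately *not* defaulted: extrapolations of
  this kind are sensitive to which limb of the profile is deemed
  linear, and published "depletion depth" statements generally do not
  record the windowing, so the package reports the fit provenance
  (slope, intercept, depths used) and leaves the window to the caller.
  Two points reduce exactly to the closed-form two-point extrapolation;
  non-decreasing profiles are flagged `no_depletion` rather than
  returning a spurious crossing.
* **Chlorophyll-a**: the widely quoted specific absorption coefficient
  "84.1" for chlorophyll-a in 90% acetone is dimensionally meaningful
  as 84.1 L g⁻¹ cm⁻¹, and that is the reading implemented
  (`A/(84.1·l)` gives g L⁻¹ of extract, then the extract-to-sample
  volume ratio scales to µg L⁻¹); the sometimes-printed
  "mL µg⁻¹ cm⁻¹" would put typical lake values nine orders of
  magnitude off. The coefficient is an argument, not a constant.

## DOM screen

Formulas are placed in van Krevelen space (H/C vs O/C) and classified
with the standard FT-ICR-MS conventions: aromatic-like when the
modified aromaticity index `AImod = (1 + C − O/2 − S − H/2)/(C − O/2 −
N − S)` exceeds 0.5, aliphatic-like when H/C ≥ 1.5 and AImod ≤ 0.5,
otherwise "other". A non-positive AImod denominator yields 0 by the
usual convention. Both thresholds are arguments. Note AImod's constant
"+1" term means the index is not exactly scale-free in the element
counts (H/C and O/C are); labels are stable under count scaling except
within 1/denominator of the 0.5 boundary.

`spearman_screen()` keeps only formulas detected (abundance > 0) at
every depth — the "present at all depths" rule — and correlates their
abundances with the CH₄ profile using average ranks. With ≤ 8 depths
the two-sided p-value is computed from the *exact permutation
distribution* (all n! covariate orderings, tie-aware); beyond that the
t approximation is used. At n = 7 the exact distribution is coarse: a
perfect monotone abundance gives p = 2/5040 ≈ 4·10⁻⁴, and the p < 0.01
bin corresponds to |ρ| ≥ 0.893. Significance bins mirror the
conventional van Krevelen colouring (strong: p < 0.005; weak:
0.005 ≤ p < 0.01; two-sided, raw p). No multiple-testing correction is
applied to the bins — that matches how such figures are drawn — but a
Benjamini–Hochberg FDR column is exposed alongside for users who want
it. `class_fraction_summary()` reports, per class, the percentage
significantly positive/negative at p < 0.01, with class sizes as
denominators and `NA` (not 0) for empty classes.

## The synthetic generator

`lake_scenario()` encodes the study conditions the package is tested
under: seven sampling depths (0, 0.5, 1, 2, 3, 4, 4.5 m), oxycline at
1.5 m, chemocline at 3.5 m, CH₄ 151 → 615 µmol L⁻¹, CO₂ 1 → 120
µmol L⁻¹, conductivity 12 → 33 mS cm⁻¹, temperature 22.4 → 20.5 °C, pH
9.61 → 9.47, O₂ 3.6 → 0.1 mg L⁻¹. Transitions are logistic across the
relevant boundary, rescaled so the end members are hit exactly at the
top and bottom of the grid; the chemocline width defaults to 0.25 m and
the oxycline to a sharper 0.15 m, as oxygen collapses over a thinner
interval than the salinity structure. A small upward CH₄ drift within
the mixolimnion (3% m⁻¹) keeps the truth profile strictly monotone, as
observed surface values (151–156 µmol L⁻¹ over the top metre) suggest.
Measurement noise is multiplicative Gaussian with relative sd 0.02 —
percent-level, the reproducibility scale of field sensors and GC
analyses — truncated at zero for concentrations (truncation events are
counted and reported).

The DOM block generates element counts per class by rejection sampling
in van Krevelen space and plants covariation: a planted fraction of
aliphatic-like formulas (default 0.275) gets abundance equal to a
rank-uniform monotone transform of the supplied profile's CH₄ plus
Gaussian coupling noise; a planted fraction of aromatic-like formulas
(default 0.34) gets the negated transform; everything else draws
independent uniform abundances. The coupling sd default (0.03 on the
unit-range signal) was fixed by a design-stage power calculation: at
n = 7 the p < 0.01 bin needs |ρ| ≥ 0.893, i.e. at most two adjacent
rank swaps, and with rank-uniform gaps of 1/6 a swap requires a noise
excursion of > 3.9 sd — so planted formulas are detected with
probability ≈ 1 while unplanted ones keep the nominal ~1% two-sided
false-positive rate. Recovery of the planted fractions within the
binomial 95% interval is then an end-to-end check of the screen, not a
tuned coincidence.

Every generator draws from its own seed stream (scenario seed + fixed
offset) and restores the caller's RNG state, so generators are pure
functions of the scenario and adding one never perturbs another's
output. Flask generation is the exact algebraic inverse of headspace
partitioning (no noise), giving a machine-precision round trip.

**What the generator does not emulate:** reactive-transport shaping of
the gas profiles (shapes are parametric logistics, not
diffusion–reaction solutions), correlated noise between variables,
depth-dependent noise, detection-limit censoring in the formula table,
intensity-dependent FT-ICR-MS noise, or any microbial-community
structure. Passing tests on synthetic data therefore demonstrates the
*computations* are correct under known ground truth — not that field
data meet the models' assumptions.

## Problem sizes and determinism

The shipped tests run the screen on 300–500 formulas over 7 depths
(exact 5040-permutation null, evaluated by one matrix product per
formula), property suites on grids of a few hundred points, and
1000-case round-trip enumerations; the whole suite completes in well
under a minute on one core. All stochastic tests fix seeds; the
acceptance script seeds from its `--seed` argument, though its four
reported quantities are deterministic.

## Known limitations

* Freshwater equilibrium constants and solubilities throughout; no
  ionic-strength or activity corrections for the hypersaline bottom
  water (affects speciation-from-pH and τ in the enhancement model, not
  the isotope balance on measured concentrations).
* Dry-pressure convention for equilibrium concentrations; moist-air
  correction would lower C_eq by ~2% at 21 °C.
* No ebullition, surface-renewal or floating-chamber flux models; the
  k600 registry is the three wind relations above.
* The depletion-depth extrapolation is a linear screen, not a transport
  model; its answer depends on the caller's window.
* Exact permutation p-values are limited to ≤ 8 depths (8! = 40320
  orderings); beyond that the t approximation is used.
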