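---
title: "Methods: methane budgets of glacial runoff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methane budgets of glacial runoff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glacialCH4)
```

This vignette documents the models behind `glacialCH4`, the assumptions they
rest on, the tunable parameters and their defaults, and the numerical choices
made where the design was genuinely open.

## Study system and scope

The package is configured around a paraglacial floodplain in southern
Iceland: a glacial melt river and a paraglacial lake at the terminus of
Sólheimajökull, sampled during high melt at water temperatures near 1 °C.
The pipeline answers one question: of the methane delivered by glacial melt,
how much escapes to the atmosphere by diffusion and how much is consumed by
microbial oxidation in the receiving waters? The same machinery applies to
any site once the configuration in `default_config()` is overridden.

## Headspace equilibration

Dissolved CH₄ is measured by equilibrating a water sample (50 mL left in a
70 mL vial) against a 20 mL ultra-pure helium headspace and reading the
headspace mole fraction `x` (ppm) by GC. `dissolved_concentration()` inverts
this with a two-reservoir mass balance at the equilibration temperature `T`
and pressure `P`:

- headspace moles: ideal gas, `x·P·Vh / (R·T)`;
- dissolved moles: Henry's law, `KH(T) · x·P · Vw`;
- original concentration: their sum over `Vw` (helium starts CH₄-free).

`KH` comes from the Wiesenburg & Guinasso Bunsen-coefficient fit at salinity
0, divided by the STP molar volume (citation in `ch4_constants$solubility`).
Assumptions: ideal-gas headspace (no fugacity correction at ambient
pressure), complete equilibration, the preservative's ~2 mL volume
displacement ignored against the 70 mL vial. The equilibration temperature
is a required input, not a constant, because samples equilibrate back in the
laboratory (20 °C default in the fixtures) rather than at stream
temperature; getting it wrong biases `KH` and therefore the partitioning.

The forward model `headspace_mole_fraction()` is the exact inverse, which
gives the package a closed-form round-trip check: partitioning a known
concentration and inverting it recovers the truth to machine precision for
any vial geometry.

## Incubation rates

Net rates at the sediment–water interface come from bottle assays: 5 mL of
sediment slurry under 70 mL of site water, triplicate bottles sacrificed at
time zero (initial) and after 21 h (river) or 22 h (lake) in situ (final).
`net_volumetric_rate()` is the mean difference per day; the sign carries the
direction (negative = net oxidation). Replicates are averaged with no
outlier rejection. The volumetric rate is re-expressed per sediment area
(`× 0.070 L / 1.32×10⁻³ m²`, the 41 mm bottle cross-section) and per
sediment mass (`× 0.070 L / (5 mL × bulk density)`); all three carry the
same sign by construction.

Two documented unit subtleties:

- The bottle water volume is 70 mL in the areal arithmetic (157.5
  µmol m⁻² d⁻¹ reproduces only with 0.070 L), although 65 mL of overlying
  water is also quoted for the assay design; the package uses 70 mL.
- The published lake areal rate of 1.9 µg CH₄ m⁻² d⁻¹ is the mass equivalent
  of the volumetric 0.12 µmol L⁻¹ d⁻¹ with the per-litre basis relabelled
  per-m²; the geometric conversion gives a different number. The package
  computes the geometric conversion and leaves the mass relabelling to
  `convert_concentration()`, so both renderings are available and neither is
  silently chosen.

These assays measure the *net* balance of methanogenesis and methanotrophy;
separating gross rates, Michaelis–Menten kinetics and oxygen dynamics are out
of scope (final O₂ of 16–17 mg L⁻¹ is metadata only).

## Gas transfer

Two k600 parameterizations, selected by environment:

- **River (energy dissipation).** `eD = g·S·v` with slope `S = 0.01` and
  velocity `v = 4 m s⁻¹` by default, then `ln k600 = 6.43 + 1.18 ln eD`
  (the high-energy-dissipation branch; the low-energy branch is deliberately
  not implemented because steep glacial channels sit far above its domain).
  Gravity defaults to 9.8 m s⁻²: with 9.8 the chain prints 205.4 m d⁻¹,
  with 9.81 it prints 205.6, and the package default follows the published
  value. It is configurable.
- **Lake (wind).** The Crusius & Wanninkhof bilinear relationship,
  `k600 = 1.0 cm h⁻¹` below a 10 m wind speed of 3.7 m s⁻¹ and
  `5.14·u10 − 17.9 cm h⁻¹` above it. At the 3.7 m s⁻¹ breakpoint this gives
  0.268 m d⁻¹, printing as 0.27 — that anchor is pinned by a test because
  the coefficients are sourced from the cited publication rather than from
  the study text.

Schmidt scaling `kx = k600 / (600/Sc)^n` converts k600 to CH₄ at ambient
temperature. `Sc` is the Wanninkhof (1992) freshwater CH₄ cubic
(coefficients and citation in `ch4_constants$schmidt`; monotone decreasing
over the −2…40 °C fit range). The exponent `n = −1/2` is the default for
both environments — appropriate for turbulent rivers and wavy, windy lakes —
and is exposed as a parameter bounded to \[−1, −1/3\]. The water temperature
used for Schmidt correction defaults to 1.0 °C, the measured incubation
water temperature; this choice reproduces the published flux digits.

## Fluxes, residence time, attenuation

The diffusive flux is `F = kx (Cw − Ceq)`. `Ceq` uses a default atmospheric
mixing ratio of 1870 ppb and 1 atm (both configurable; at ~0.005 µM, `Ceq`
is two orders of magnitude below the river concentration, so the headline
excess values are insensitive to the exact choice). Dimensionally, m d⁻¹
times mmol m⁻³ is mmol m⁻² d⁻¹; areal methane fluxes circulate in the
literature on both the mmol and µmol scale, and the two renderings of the
published values are inconsistent with each other by 10³, so
`diffusive_flux()` returns both scales explicitly and
`oxidation_vs_emission()` refuses to compare areal rates without an explicit
scale argument.

Residence time assumes hydraulic continuity: `τ = L / (Q/(w·d))` over the
4 km × 20 m × 1 m reach, 27 min at the 50 m³ s⁻¹ summer discharge and
133 min at the 10 m³ s⁻¹ winter discharge.

Attenuation is zero-order: a constant volumetric oxidation rate acting for
the transit time, `removed = min(rate·τ, C0)`, clamped so mass is conserved.
Zero-order kinetics is the design choice because the headline estimates
multiply a fixed measured rate by residence time; it ignores substrate
limitation and the re-aeration a flowing river experiences, so it is an
upper bound on removal at low concentrations. One rounding chain is
reproduced deliberately: the published 11 %/53 % reductions arise from
rounding the removed mass to two decimals (0.055 → 0.06, 0.275 → 0.28)
before dividing by the 0.53 µM load; `attenuate()` returns the raw fractions
(10.4 %, 51.9 %) and the rounded-chain fractions side by side, labelled, and
reports removed and remaining separately because "reduced to 0.06–0.28 µM"
is ambiguous between the two.

## Upscaling

`per_area_flux()` divides each glacier's annual CH₄ export by its area
(Leverett 6.3 Mg yr⁻¹ / 20 km²; Svalbard archipelago 2310 Mg yr⁻¹ /
6268 km²; Sólheimajökull 2460 Mg yr⁻¹ / 9 km², the 41 Mg d⁻¹ river flux
over a 60-day melt season). `global_upscale()` multiplies by the 680,000 km²
global glacierized area. Raw doubles are retained everywhere; the published
renderings round two of them differently (0.3685 → 0.36, 185.87 → 185), and
the comparison table in `run_scenario()` carries those reference figures
with explicit tolerances rather than reproducing their rounding. No
uncertainty propagation is attempted — the extrapolation spans three orders
of magnitude between source glaciers, which is the point the comparison
makes.

## Synthetic data

`synthetic_scenario()` emulates the structure of the deposited measurement
data: triplicate headspace vials and triplicate initial/final incubation
bottles per site, with known ground truth. Defaults mirror the study
conditions: river 0.536 µM and −2.97 µmol L⁻¹ d⁻¹ over 21 h, lake 0.23 µM
and +0.12 µmol L⁻¹ d⁻¹ over 22 h. The incubation bottles start at their own
initial concentrations (3.0 µM river, 1.0 µM lake) because sediment-slurry
water is far above ambient stream water — and because a 0.536 µM start
cannot physically sustain a 2.6 µM drawdown. Noise is additive Gaussian on
concentration with `noise_sd = 0.02 µM` (a few percent of the river
concentration, typical of GC headspace precision; no analytical error model
is published), applied before forward-partitioning so the noiseless
generator/estimator pair is an exact identity. A single seed threads all
draws; identical seeds give byte-identical files.

What the generator does *not* emulate: GC chromatograms and calibration
error, spatial or temporal autocorrelation, re-aeration during incubation,
non-Gaussian outliers. Passing the recovery tests therefore demonstrates
that the estimators are correct and unbiased under the stated noise model,
not that field data are this well behaved.

## Reproduction pipeline and problem sizes

`run_scenario(default_config())` executes all stages in dependency order and
compares 18 derived quantities against their published reference values,
each with an explicit absolute tolerance: half a unit in the last printed
digit, widened (and commented in the source) only for the documented
rounding-chain quantities. When the config names headspace/incubation CSVs,
the measured concentrations and rates are re-estimated from those files
instead of taken from the config.

Test and acceptance problem sizes: round-trip property grids of a few dozen
cases, 200 simulated triplicate assays for the parameter-recovery check
(mean estimate within 2 standard errors of truth), and one simulated
campaign (18 vials + 12 bottles) for the end-to-end acceptance run — the
full suite runs in seconds.

## Known limitations

- Salinity is fixed at 0; no other gases beyond what Schmidt normalization
  requires.
- Zero-order attenuation has no longitudinal transport, resupply, or
  substrate limitation.
- The lake excess concentration (0.34 µM) is carried as an input because the
  published lake concentrations (3.3–4.1 µg L⁻¹ ≈ 0.21–0.26 µM) are not
  mutually consistent with it; the package does not guess which is right.
- Upscaling is a linear extrapolation with no uncertainty bounds.
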