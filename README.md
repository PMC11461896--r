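# glacialCH4

Methane budgets of land-terminating glacial runoff: from raw headspace gas
chromatography and sediment incubation measurements to diffusive emission
fluxes, reach-scale oxidation, and global upscaling.

## The problem

Glacial melt can carry high loads of dissolved methane, but how much of it
reaches the atmosphere depends on two competing paths at the glacier margin:
diffusive evasion across the air–water interface and microbial oxidation
(methanotrophy) in paraglacial river and lake sediments. Quantifying that
balance requires chaining several standard aquatic-biogeochemistry
calculations that are usually scattered across spreadsheets:

1. **Headspace equilibration** — recover the dissolved CH₄ concentration of a
   water sample from the mole fraction measured by GC after the sample
   equilibrates with an ultra-pure helium headspace. The mass balance combines
   the ideal gas law for the headspace with Henry's law (Wiesenburg &
   Guinasso freshwater solubility) for the water phase:
   `n_total = x·P·Vh/(R·T) + KH(T)·x·P·Vw`, and the original concentration is
   `n_total / Vw`.
2. **Incubation rates** — net methane production or oxidation from initial vs
   final bottle concentrations: `rate = (mean(final) − mean(initial)) / days`,
   expressed per litre of water, per m² of sediment
   (`rate · V_water / A_sediment`) and per gram of sediment
   (`rate · V_water / (V_sed · ρ_bulk)`).
3. **Gas transfer velocity** — for steep rivers, energy dissipation
   `eD = g·S·v` and the high-energy scaling `ln k600 = 6.43 + 1.18 ln eD`
   (Ulseth et al.); for lakes, the Crusius & Wanninkhof bilinear wind
   relationship. Both are Schmidt-scaled to CH₄ at ambient temperature:
   `kx = k600 · (Sc_CH4/600)^(−n)` with `n = −1/2` (Wanninkhof Schmidt
   polynomial).
4. **Diffusive flux** — thin boundary layer model `F = kx · (Cw − Ceq)`.
5. **Reach attenuation** — residence time `τ = L / (Q / (w·d))` and zero-order
   removal `removed = min(rate · τ, C0)`.
6. **Upscaling** — per-glacier annual flux / glacier area, extrapolated to the
   global glacierized area (680,000 km²).

The package implements each stage as a tested function, ships a synthetic-data
generator with known ground truth (so the whole chain is verifiable offline),
and a `run_scenario()` pipeline that reproduces every headline number of the
Icelandic paraglacial study system it is configured for.

## Worked example

```r
library(glacialCH4)

# river gas transfer: slope 0.01, velocity 4 m/s, water at 1 degC
gt <- gas_transfer_estimate("river_energy_dissipation", temperature_c = 1,
                            slope = 0.01, velocity = 4)
gt
#> Gas transfer (river_energy_dissipation):
#>   k600 = 205.4 m d-1, Sc = 1786.8, n = -0.5, kx = 119 m d-1

# diffusive flux from the measured excess concentration
diffusive_flux(gt$kx, excess_um = 0.53)
#> Diffusive CH4 flux: 63.08 mmol m-2 d-1 (= 6.308e+04 umol m-2 d-1)
#>   kx = 119 m d-1, excess = 0.53 uM

# net oxidation measured in a sediment incubation (3.0 -> 0.4 uM in 21 h)
net_rate(incubation_assay("river", c(3, 3, 3), c(0.4, 0.4, 0.4),
                          duration_h = 21))
#> Net CH4 rate at river (net oxidation):
#>       -2.97 umol L-1 d-1
#>        -158 umol m-2 d-1
#>     -0.0433 umol g-1 d-1

# how much of the methane load is oxidized in transit through a 4 km reach?
tau <- residence_time(reach_scenario(4000, 20, 1, discharge_m3_s = 10))
attenuate(c0 = 0.53, oxidation_rate = 2.97, tau_min = tau)
#> Reach attenuation: removed 0.275 uM, remaining 0.255 uM (51.9% removed;
#>   53% with removed mass rounded to 2 d.p.)
```

The numbers mean: a steep glacial melt river has an extremely high gas
transfer velocity (k600 ≈ 205 m d⁻¹), so its modest supersaturation
(0.53 µM) still drives a large diffusive flux; at the same time the river
sediments oxidize methane at 2.97 µmol L⁻¹ d⁻¹, enough to remove roughly
half of the methane load during the ~2 h winter transit of the reach.

The full reproduction report (gas transfer, fluxes, residence times,
attenuation, areal oxidation and the glacier upscaling table, each compared
to its published reference value at an explicit tolerance):

```r
res <- run_scenario(default_config())
res$report          # 18 quantities, all within tolerance
res$upscaling       # per-glacier flux densities and global extrapolations
```

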