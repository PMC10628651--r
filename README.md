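# phycofilm

Quantitative analysis of phototrophic (microalgal) biofilms grown under
square-wave light/dark cycles, for people who run flow-cell or rotating
biofilm photobioreactors and need to turn raw light, fluorometry and
confocal measurements into growth rates, photoinhibition diagnostics and
productivity predictions.

A light/dark regime delivers a peak PPFD `I_peak` for `T_L` seconds out
of every cycle of `T = T_L + T_D` seconds, so the duty cycle is
ε = T_L/T and the average dose is `I_ave = I_peak · ε`. The package
covers the full analysis chain:

- **Growth from transmittance.** Under the Lambert–Beer law
  `I_out = I_in · exp(−kX)`, the double log `ln(ln(I_in/I_out))` is
  linear in time with slope equal to the net specific growth rate μ —
  independent of the extinction coefficient k. `fit_growth_rate()`
  reports the maximum-slope regression window (≥ 4 points).
- **Haldane growth–irradiance model.** Gross light-phase rate
  `μ_L(I) = μ_max·I / (I + (μ_max/α)(I/I_opt − 1)²)`, fitted by
  Nelder–Mead least squares (`fit_haldane()`), with the
  intermittent-light extension `μ = μ_L(I_peak)·ε − R` and its inverse
  `μ_L = (μ + R)/ε` for detecting photoinhibition mitigation by fast
  cycling.
- **Reactor predictions.** Growth yield `μ/I_ave` and footprint
  productivity `P_f = μ·(S_T/S_f)·ρ·h` with `S_T/S_f = 1/ε`
  (`productivity_scan()`).
- **PAM fluorometry.** Fv/Fm, ΔF/Fm′, `rETR = ΔF/Fm′·PAR·0.5`, and the
  rectangular-hyperbola rapid-light-curve fit giving rETR_max, α and
  `E_k = rETR_max/α` (`fit_rlc()`).
- **Morphometrics & 3D structure.** 8-connected particle areas,
  sphere-equivalent cell volumes, chlorophyll-a from 665/649 nm
  absorbances, and COMSTAT-style biovolume / thickness / roughness on
  binary confocal stacks with the clustered-vs-layered slope diagnostic
  (`structure_metrics()`, `cluster_slope()`).
- **Synthetic data.** Seeded generators (`scenario_config()`, `gen_*`)
  emulate the whole experimental design so every estimator is testable
  without instrument data.

## Worked example

```r
library(phycofilm)

## the flow-cell channel and its hydraulics
fc <- flow_cell(length = 40, width = 6, height = 3, flow_rate = 0.1)
fc
#> Flow-cell channel 40 x 6 x 3 mm, flow 0.1 mL/min
#>   mean velocity 0.0926 mm/s, Re 0.37, wall shear 0.185 mPa

## a Haldane model with its optimum at the average dose: strong
## photoinhibition at a 300 peak
p <- haldane_params(mu_max = 0.55, alpha = 0.005, I_opt = 100)
haldane_mu(300, p)          # 0.223 d^-1 — less than half of mu_max
net_growth(310, p, epsilon = 1/3, R = 0.05)
#> 0.0215  — the no-mitigation prediction for a 1/3 duty cycle

## the full synthetic demonstration pipeline
run <- run_pipeline(seed = 1)
run$mitigation[, c("label", "mu_L_observed", "mu_L_continuous",
                   "mitigation_ratio")]
#>            label mu_L_observed mu_L_continuous mitigation_ratio
#>         100 cont         0.599           0.565             1.06
#>     300-5s-0-10s         0.603           0.255             2.36
#>    300-30s-0-60s         0.330           0.255             1.29
#>  300-1min-0-2min         0.426           0.255             1.67
#>     500-5s-0-20s         0.674           0.153             4.41
```

Reading the table: under continuous light the observed gross rate sits
on the Haldane curve (ratio ≈ 1). The 15 s cycle at a 310 peak sustains
a gross light-phase rate 2.4× the continuous-light rate at that same
peak — fast cycling lets the cells grow on the *average* light and
escape photoinhibition — while the 3 min cycle mitigates much less. The
productivity consequence: at ε = 1/3 a rotating reactor carries 3× more
biofilm per footprint, e.g.
`footprint_productivity(0.2, reactor_spec(1/3))` → 8.4 g m⁻² d⁻¹.

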