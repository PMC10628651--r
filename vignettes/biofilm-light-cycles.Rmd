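---
title: "Modelling microalgal biofilm growth under light/dark cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling microalgal biofilm growth under light/dark cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycofilm)
```

## The problem

Phototrophic biofilms in rotating reactors experience square-wave
light/dark (L/D) cycles: a patch of biofilm is illuminated at a peak
photosynthetic photon flux density (PPFD) `I_peak` for `T_L` seconds per
revolution and spends the rest of the cycle (`T_D` seconds) in darkness.
Such a regime is summarised by its duty cycle
$\varepsilon = T_L/(T_L + T_D)$, cycle time $T = T_L + T_D$ and
time-averaged PPFD $I_{ave} = I_{peak}\,\varepsilon$. Cycling dilutes
light in time: a regime can deliver a moderate average dose while the
instantaneous peak is well into the photoinhibiting range. The package
quantifies how *Chlorella vulgaris*-type biofilms grow, photosynthesise
and organise under such regimes, and what that implies for reactor
productivity.

## Growth estimation from light transmittance

Light transmission through the biofilm follows the Lambert–Beer law,
$I_{out} = I_{in} e^{-kX}$ with areal biomass $X$ (g m$^{-2}$) and
extinction coefficient $k$ (m$^2$ g$^{-1}$). Hence
$\ln\ln(I_{in}/I_{out}) = \ln k + \ln X$, which under exponential growth
is linear in time with slope equal to the net specific growth rate
$\mu$ — independently of $k$, which never needs to be known.
`fit_growth_rate()` scans every contiguous window of at least four
usable points and reports the maximum ordinary-least-squares slope
("maximum slope with at least four data points"), with ties broken
toward the longer window and then the earlier start so the choice is
deterministic. Points without attenuation ($I_{out} \ge I_{in}$, e.g. a
clean flow-cell on day 0) leave the double logarithm undefined; they are
excluded with a warning rather than clamped, since clamping would bias
the slope. Transmitted light measured at several positions is averaged
*before* the transform, matching the mean-of-positions convention of the
attenuation measurement itself.

Because the estimator takes a maximum over windows, sensor noise
inflates it slightly; the effect shrinks quickly with the number of
positions averaged and with the attained attenuation. The package's own
robustness property (2 % multiplicative sensor noise, 15 daily points,
three positions) is therefore stated about the *distribution* of
estimates — mean estimate and median absolute error within 10 % of the
generating rate — not about every individual replicate.

## The Haldane model and its intermittent-light extension

Gross growth during light phases is modelled by the Haldane
(substrate-inhibition) growth–irradiance curve

$$\mu_L(I) = \frac{\mu_{max}\, I}{I + \frac{\mu_{max}}{\alpha}
  \left(\frac{I}{I_{opt}} - 1\right)^2},$$

which rises with initial slope $\alpha$, peaks at exactly
$\mu_{max}$ when $I = I_{opt}$, and declines beyond it
(photoinhibition). We store $\alpha$ in d$^{-1}$ per unit PPFD
(d$^{-1}$ µmol$^{-1}$ m$^2$ s), the unit that makes the formula
dimensionally consistent as an initial slope of rate versus irradiance.
With a constant respiration rate $R$ (d$^{-1}$) running in light and
darkness, the net rate under an intermittent regime — *if* the light
phase simply ran at the continuous-light rate of the peak — is

$$\mu(I) = \mu_L(I_{peak})\,\varepsilon - R,$$

the "no-mitigation" prediction. Its algebraic inverse,
$\mu_L = (\mu + R)/\varepsilon$ (`gross_light_rate()`), converts
measured net rates into gross light-phase rates; measured $\mu_L$ values
exceeding the continuous-light curve at the same peak indicate that fast
cycling mitigates photoinhibition. `compare_predictions()` reports this
as the mitigation ratio $\mu_L^{obs}/\mu_L^{cont}(I_{peak})$.

`fit_haldane()` minimises squared residuals with the derivative-free
Nelder–Mead simplex. The three parameters are optimised on the log scale,
which enforces positivity without constraints and keeps the simplex away
from invalid regions. Starting values are the conventional heuristics
(largest observed rate, its light level, slope of the two lowest-light
points); the tolerance is $10^{-8}$ on parameters and objective with at
most 5000 iterations, and the optimum is polished by one restart — a
standard guard against premature simplex collapse. Non-convergence is
warned about, never silent. Fits are invariant to point order and to
affine rescaling of the light unit (with parameters rescaling
accordingly), which the test suite checks.

Reactor predictions build on the fitted model: growth yield
$\mu/I_{ave}$ and footprint productivity
$P_f = \mu\,(S_T/S_f)\,\rho\,h$ with $S_T/S_f = 1/\varepsilon$ enforced
(a rotating system at duty cycle $\varepsilon$ carries $1/\varepsilon$
times more biofilm than its illuminated footprint). Defaults are a
dry-weight biomass density $\rho = 1.40\times 10^5$ g m$^{-3}$ and a
biofilm thickness $h = 10^{-4}$ m (100 µm, a typical mature maximum
thickness at this scale); $R$ defaults to 0.05 d$^{-1}$, a nominal dark
respiration rate for *C. vulgaris*. All three are plain arguments — they
are configuration, not constants, and any serious use should supply
system-specific values.

## PAM fluorometry and rapid light curves

From a dark-adapted trace, `fv_fm()` gives the maximum PSII quantum
yield $(F_m - F_0)/F_m$ (healthy cultures: 0.7–0.8) and
`effective_yield()` the in-light yield $(F_m' - F)/F_m'$. The relative
electron transport rate is $rETR = \Delta F/F_m' \times PAR \times 0.5$,
the factor 0.5 assuming two photons per electron transported.
`fit_rlc()` fits the two-parameter saturating exponential (the
"rectangular hyperbola" of light-curve practice)
$rETR = rETR_{max}(1 - e^{-\alpha\,PAR/rETR_{max}})$ by the same
simplex settings as the Haldane fit, and derives the saturation
irradiance $E_k = rETR_{max}/\alpha$ exactly. The dark step (PAR = 0,
rETR = 0) is included by default — it anchors the curve at the origin —
and can be dropped with `include_zero = FALSE`; per-point weights are
accepted, since instrument fits differ on both conventions. No
photoinhibition ($\beta$) term is included: the reported parameters are
$rETR_{max}$, $\alpha$ and $E_k$ only.

## Morphometrics and 3D structure

`particle_areas()` labels 8-connected foreground components (the
particle-analysis default of ImageJ-style tools) and returns physical
areas; touching cells merge — a documented limitation, as no watershed
splitting is attempted — and border particles are retained.
`cell_volume()` converts a projected area to the sphere of that
cross-section, $V = \frac{4}{3}A\sqrt{A/\pi}$. Chlorophyll-a follows
the DMSO-extract equation $12.19\,A_{665} - 3.45\,A_{649}$ µg mL$^{-1}$,
normalised per cell and per cell volume by `normalize_chl()`.
`areal_density()` takes the substratum area as an explicit argument
because published channel areas are inconsistent between geometric
(2.4 cm$^2$ for a 40 × 6 mm channel) and effective sampling values
(0.24 cm$^2$); the choice is the user's.

For binary confocal stacks, `biovolume()` is occupied-voxel volume per
substratum area; `thickness_map()` measures each column from the
substratum to its highest occupied voxel (internal voids included, the
COMSTAT height convention), so biovolume and mean thickness coincide
exactly only for void-free columns; and `roughness()` is the COMSTAT
roughness coefficient $R_a^* = \frac{1}{N}\sum_i |L_i - \bar L|/\bar L$,
0 for a flat film with supremum $2(N-1)/N < 2$. All columns enter the
sum by default, empty ones at $L = 0$ (`occupied_only = TRUE` gives the
alternative, as the variant is not standardised). No intensity
thresholding or connected-volume filtering is performed — stacks arrive
binary, and autofluorescence-derived voxels are biomass proxies, not
cell counts. `cluster_slope()` regresses maximum thickness on biovolume
over early development: a steep slope signals clustered (vertical
colony) growth, a flat or negative slope conformal layer growth.

## The synthetic scenario

`scenario_config()` fixes the study conditions the generators emulate:
the five reference illumination programs (continuous ~100 plus four
intermittent regimes with peaks ~300/~500, duty cycles 1/3 and 1/5 and
cycle times 15 s–3 min, all at ~100 average), 15 days of daily sampling,
and transmitted light read at three positions. Ground truth for the
Haldane model is $\mu_{max} = 0.55$ d$^{-1}$, $I_{opt} = 100$
µmol m$^{-2}$ s$^{-1}$, $\alpha = 0.005$ d$^{-1}$ per unit PPFD: the
optimum sits at the experiment's average PPFD, so peaks of 300–500 are
strongly photoinhibiting — the situation the design probes. The
extinction coefficient ($k = 0.15$ m$^2$ g$^{-1}$) and inoculum biomass
($X_0 = 1$ g m$^{-2}$) give ~14 % day-0 attenuation rising toward
saturation within the run, the measurable range of the method.

Noise models are conventional: multiplicative lognormal
($\sigma = 0.02$) for light sensors, additive truncated Gaussian for
PAM yields, Gaussian lateral jitter for layered stacks. Mitigation is
emulated with a light-integration weight $m = e^{-T/\tau_I}$,
$\tau_I = 60$ s: fast cycles ($T$ of tens of seconds) approach full
light integration (growth on the *average* light), slow cycles approach
no integration (growth on the peak), which reproduces a >2× gross-rate
mitigation ratio for the 15 s cycle. Every generator is a deterministic
function of (config, seed), and each generator's output passed through
its analysis counterpart at zero noise returns the generating
parameters — the package's core closure property.

What the generators do *not* emulate: within-biofilm light gradients,
EPS, photoacclimation dynamics, realistic confocal point-spread
rendering, or cell segmentation from grayscale images. Passing tests
therefore validate the estimators and the algebra chain on data with
the assumed statistical structure, not the biology of any particular
experiment.

## Numerical choices and problem sizes

Demo stacks are 64 × 64 × 16 voxels at the reference voxel dimensions
(1.25 µm lateral, 3.94 µm axial) and masks 256 px — sizes chosen so the
full pipeline and test suite run in seconds while every metric is
exercised against brute-force voxel oracles; all functions accept
full-size 512 × 512 stacks unchanged. The end-to-end demonstration
(`run_pipeline()`) derives one sub-seed per stage from its master seed,
so runs are bit-reproducible; its report writes growth estimates per
regime, the Haldane fit, the mitigation table, the productivity scan
and structural metrics.

## Known limitations

The maximum-slope window estimator is upward-biased under noise (see
above); the respiration rate is treated as constant although it likely
varies with light history; the wall-shear value uses the parallel-plate
approximation, which can disagree substantially with published values
for the same geometry whose derivation is unstated; merged touching
cells inflate particle areas; and the roughness coefficient's exact
column convention varies between tools, so both conventions are
exposed.
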