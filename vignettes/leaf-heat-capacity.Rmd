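---
title: "Estimating leaf specific heat capacity from thermal transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf specific heat capacity from thermal transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafcp)
```

## The model

A leaf (or reference plate) exposed to a short light pulse stores part of the
absorbed energy and re-releases it through long-wave radiation, sensible heat
and transpiration. The temperature of the object follows

$$\frac{dT_{leaf}}{dt} = \frac{\alpha I_s
  + 2\varepsilon\theta\,(T_{reflect}^4 - T_{leaf}^4)
  - 2\rho_{air} C_s g_{bh}\,(T_{leaf} - T_{air})
  - 2\lambda\,\frac{0.622\,\rho_{air}}{P_{atm}}\,
    \frac{1}{1/g_{sw} + 1/g_{bw}}\,\mathrm{VPD}}{k}$$

where $k = lt \cdot \rho \cdot C_p$ (J m⁻² K⁻¹) is the areal heat capacity.
Long-wave, sensible and latent exchange act on both leaf faces (factor 2);
the short-wave pulse is absorbed on the lit face only. The boundary layers
for heat and water vapour are related by $g_{bh} = 0.92\,g_{bw}$ in laminar
flow. During the pulse the initial slope is $\alpha I_s / k$ (the loss terms
still cancel at the pre-pulse equilibrium), which is what makes a transient
experiment informative about $k$: with a fresh mass per unit area measured as
fresh weight over leaf area, $C_p = k / (\rho\,lt)$ follows directly.

Assumptions worth keeping in mind: the object is laterally isothermal (no
within-leaf gradients), conductances are constant over the two-minute
protocol, the surroundings radiate at a single temperature `T_reflect`
(measured from a crumpled foil imaged at emissivity 1), and view factors are
ignored.

## Parameters, constants and defaults

| quantity | default | unit | why |
|---|---|---|---|
| $C_s$ (humid-air heat capacity) | 1010 | J kg⁻¹ K⁻¹ | ~20 °C value; the model treats it as a coefficient and its influence is second order. Override via `physics_constants()`. |
| $\lambda$ (latent heat) | 2.45×10⁶ | J kg⁻¹ | 20 °C value; same reasoning. |
| $\rho_{air}$ | ideal gas at $(T_{air}, P_{atm})$ | kg m⁻³ | recomputed at every instant; specific gas constant 287.05 J kg⁻¹ K⁻¹. |
| saturation vapour pressure | Tetens (over water) | Pa | no formula is prescribed by the method itself; Tetens and Buck agree to ~0.1 % over 0–45 °C and both are exposed (`es_formula`). |
| $g_{sw}, g_{bh}$ priors | half-normal(0, 0.005) | m s⁻¹ | the broadly chosen conductance priors of the method, truncated at 0 as physics requires. |
| $k$ prior | half-normal(0, 5000) | J m⁻² K⁻¹ | our choice (the source method states none): covers plates (~3000) and leaves (~200–25 000) without being informative. |
| $\sigma_{obs}$ prior | half-normal(0, 0.5) | K | our choice; the residual sd is estimated, not fixed. |
| sampling rate | 25 Hz recorded, decimated to 5 Hz for fitting | Hz | 5 Hz changes the posterior negligibly and cuts the likelihood cost five-fold; configurable (`decimate_hz`). |
| integration tolerances | rtol = atol = 10⁻⁸ | – | adaptive RK45 with steps split at light-switch boundaries, because discontinuous forcing breaks naive adaptive stepping. |

The molar conversion of a conductance is $g \cdot P_{atm}/(R\,T_{leaf})$. For
stomatal conductance the convention quoted with the model carries an extra
factor 0.92 in the conversion factor; whether that factor is intended is
ambiguous, so `conductance_to_molar()` exposes both variants via
`include_092` and the internal model never depends on the choice (it works in
m s⁻¹ throughout).

A note on the reference plate: the published constants (thickness 0.001335 m,
density 2484 kg m⁻³, C_p 896 J kg⁻¹ K⁻¹) multiply to k = 2971.3 J m⁻² K⁻¹,
slightly different from the rounded 2968 sometimes quoted; the package always
derives k from the triple rather than hard-coding the rounded value.

## Inference

`fit_transient()` samples $(k, g_{bh}, g_{sw}, \sigma_{obs})$ — with $g_{sw}$
pinned to zero for a dry plate — by adaptive random-walk Metropolis on the
log scale (proposal covariance and scale adapted during warmup only, frozen
afterwards). The likelihood compares the *integrated* model temperature to
the observations; the smoothing-spline derivative route
(`spline_derivative()`) is provided as a diagnostic and initializer, not as
the likelihood, since the estimation target is the match between modelled and
observed temperature. Chains start from physical heuristics: $k_0 = \alpha
I_s/\text{onset slope}$, $g_{bh,0}$ from the post-pulse decay time constant,
$g_{sw,0}$ from the dark equilibrium offset below air temperature.

Any correct MCMC scheme satisfies the contract; the shipped sampler is
validated by rank-normalized split R-hat < 1.01 and bulk ESS > 200 on every
free parameter (computed in `convergence_diagnostics()`), and a fit failing
either is *flagged*, never silently returned. Note that a random-walk sampler
needs more iterations than a Hamiltonian one for the same ESS: the reference
budget of 4 × 1000 iterations (500 warmup) typically must be raised to
roughly 4 × 3000 here. The 95 % intervals are equal-tailed quantiles of the
pooled post-warmup draws, and the C_p interval is the k interval divided by
the mass per area (a monotone transform of the draws).

The initial model temperature is taken as the mean of the pre-pulse
observations (falling back to the first sample), so a ~10 s dark baseline
before the pulse is recommended. Degenerate inputs behave predictably:
a protocol with no lit segment leaves k unidentified (warned and flagged);
zero stomatal conductance simply switches off the latent flux (the series
conductance limit is defined as 0, no division error).

## What the synthetic data emulate — and what they do not

`generate_synthetic_transient()`, `aluminum_fixture()` and `leaf_fixture()`
reproduce the stated measurement world: a 10 s, 270 W m⁻² pulse with 110 s
darkness for leaves (60 s / 9 min for the plate), 25 Hz sampling (plate
fixtures default to the 5 Hz fitting rate), additive i.i.d. Gaussian sensor
noise of 0.05 K — between the camera noise floor (NETD < 30 mK) and
thermocouple noise (~0.2 K) — and a fan-stirred enclosure at 20 °C. Values
the source does not state were fixed once at realistic lab values and are not
tuning knobs: relative humidity 50 %, `T_reflect = T_air`, boundary-layer
conductance 0.01 m s⁻¹ (consistent with ~0.2 m s⁻¹ wind over a small frame).

The generator does *not* emulate spatial temperature gradients, camera drift
or 1/f noise, vignetting, emissivity mis-specification, or stomatal dynamics
during the pulse. A green parameter-recovery test therefore establishes that
the inversion is correct and well calibrated *under the model's own
assumptions*; it cannot establish robustness to violations of them — that is
precisely what the sensitivity analysis quantifies for the input side.

## Sensitivity analysis

`cp_sensitivity_table()` re-estimates C_p with one input at a time perturbed
by ±10 % while the observed trace is held fixed, matching the published
procedure of full refits rather than derivative approximations. Temperatures
are perturbed on the **Celsius** scale (a −10 % change at 22 °C is −2.2 °C),
which the reported numbers imply; everything else scales on its natural
scale. The MCMC seed is held fixed across refits so differences are not
inflated by sampler noise. On the plate fixture the pattern is: irradiance
and absorptance ≈ ±10 % (C_p scales with assumed absorbed energy), thickness
≈ ∓10 % (it only enters the k→C_p division), humidity and emissivity
negligible, while −10 % `T_reflect` or `T_air` inflate C_p by tens of percent
— the environment temperatures must be measured carefully. Since the plate's
baseline air/humidity conditions are not published, the reproduced
temperature-factor magnitudes are approximate (our fixture gives ~+44 % for
−10 % `T_reflect`, above the published 20–25 % band, which the acceptance
rule treats as a lower bound of 15 %).

A perturbed absorptance of 0.98 × 1.1 = 1.078 exceeds the physical range;
`perturb_inputs()` deliberately constructs such states (`strict = FALSE` in
`optical_properties()`) because the analysis asks what an *erroneous* input
does to the estimate.

## Numerical choices

- Adaptive Cash–Karp RK45 in compiled code; steps never cross a protocol
  boundary, so irradiance discontinuities are exact. Verified against a 1 ms
  fixed-step RK4 oracle written in pure R against the R flux functions
  (max |ΔT| < 10⁻³ K).
- `equilibrium_temperature()` brackets the root in [T_air − 30, T_air + 50] K
  and polishes it to |rhs| < 10⁻¹⁰, erring with diagnostics if the bracket
  has no sign change.
- `smooth.spline` with GCV chooses the spline smoothness; near light
  switches the derivative estimate is biased over roughly ±3 s, so estimates
  there should not be trusted (the likelihood route is unaffected).
- Light-onset detection uses a 5-sample local-linear slope; pick a threshold
  well above the noise slope and below $\alpha I_s / k$ of the reference
  tape.

## Limitations

- Single-transient, single-leaf fits only; no hierarchical pooling across
  replicates.
- The conductances are assumed constant over the two-minute protocol; strong
  stomatal responses to the pulse would bias g_sw (not k, which is set by the
  fast initial response).
- C_p accuracy is bounded by the accuracy of irradiance, absorptance and the
  fresh mass per area — each propagates roughly one-to-one — and by the
  environment temperature sensors (strongly amplified, see the sensitivity
  table).
- The image-processing side (ROI extraction from thermograms) is out of
  scope; the package starts from extracted temperature time series.
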