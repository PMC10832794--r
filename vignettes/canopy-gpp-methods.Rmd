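---
title: "Methods: multi-angle PRI/SIF retrieval and GPP estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-angle PRI/SIF retrieval and GPP estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyGPP)
```

## Overview

`canopyGPP` estimates rice-canopy gross primary productivity from
multi-angle hyperspectral observations. The chain is: per-angle
reflectance, PRI, and 3FLD SIF retrieval; angular normalization by a
kernel-driven BRDF fit evaluated at the hotspot; a two-leaf
(sunlit/shaded) decomposition giving LAI-weighted canopy totals;
eddy-covariance screening and Van't Hoff partitioning of NEE into Re
and GPP; and linear PRI/SIF → GPP regression with held-out-day
validation. This vignette describes each model, its assumptions, the
tunable parameters, and the numerical choices, and explains what the
synthetic-data generator does and does not emulate.

## Spectral retrieval

Reflectance uses the whiteboard correction in its product form,
$R(\lambda) = L\,L' / (E\,E')$, with $L, E$ the canopy-reflected
radiance and downwelling irradiance and $L', E'$ the synchronous
reference-panel pair. With a pre-calibrated instrument
(`identity_calibration()`) this reduces to $R = L/E$. Reflectance
outside $[0, 1]$ is flagged in a QC mask, never clipped, so downstream
fits see unbiased noise.

PRI is $(R_{531} - R_{570})/(R_{531} + R_{570})$. Band values are the
mean of all grid samples within ±1 nm of the band center (the
`bandwidth` argument); instruments with coarser sampling can widen
this. Wavelength grids must agree sample-by-sample to within 0.5 nm —
a coarser mismatch is treated as an error rather than silently
interpolated, because interpolation across the O₂-A line would bias
the SIF retrieval.

SIF uses three-band Fraunhofer Line Discrimination at the O₂-A
absorption feature: in-band 762 nm, outer bands 758 and 769 nm, with
outer-band weights $\omega_{left} = (\lambda_r - \lambda_{in}) /
(\lambda_r - \lambda_l)$ (here 7/11 and 4/11). The retrieval
$\mathrm{SIF} = (E_{out} L_{in} - E_{in} L_{out}) / (E_{out} -
E_{in})$ is algebraically exact whenever reflectance and fluorescence
are spectrally constant across the three bands — the property the
acceptance checks exercise over random spectra. Negative retrievals
are physically impossible but statistically expected under noise; they
are kept and QC-flagged (clipping them would bias the BRDF fit).

## Kernel-driven BRDF and the hotspot

Each half-hour angular index field is fitted with
$\rho(\theta_v, \theta_s, \Delta\phi) = k_i + k_g K_L + k_v K_R$,
where $K_R$ is the Ross–Thick volumetric kernel and $K_L$ the
non-reciprocal Li–Sparse geometric kernel with crown shape parameters
$h/b = 2$, $b/r = 1$ — the conventional defaults for low, dense crop
canopies; both are configurable. The fit is ordinary least squares on
$[1, K_L, K_R]$; the design-matrix condition number and residual RMS
are reported, and fits with condition number above $10^6$ or fewer
than 30 directions are flagged low-quality (the angular design here —
31 azimuths × 7 zeniths — is far from these limits). The hotspot is
the exact sun–view coincidence $\theta_v = \theta_s, \Delta\phi = 0$;
no hotspot-broadening kernel is added, because the scan grid (10°
steps) cannot constrain a sub-degree hotspot width. Values requested
beyond the 60° measured zenith range are returned with an
extrapolation warning.

## Two-leaf decomposition

What a sensor sees at each angle is a mixture of sunlit leaves, shaded
leaves, and background. The background fraction is the gap fraction
$P_{VG} = e^{-0.5\,\Omega\,\mathrm{LAI}/\cos\theta_v}$ with clumping
index $\Omega = 0.9$; the sunlit fraction is the ratio of the
per-angle canopy reflectance at 670 nm to the leaf-level reflectance
at 670 nm (a pluggable scalar, default 0.05, as produced by a PROSPECT
run for rice — radiative-transfer modelling itself is out of scope);
the shaded fraction closes the sum to one. $P_T$ is clamped into
$[0, 1 - P_{VG}]$ with clamping logged. The per-angle mixture
$\rho_{obs} = P_T \rho_{sun} + P_S \rho_{sh}$ is solved by unweighted
least squares without intercept over the rotation cycle; unweighted
because per-angle quality weights are not available from a single
scan. Negative SIF component solutions are clamped to zero with a QC
flag (configurable); PRI components are naturally negative and never
clamped.

Sunlit and shaded leaf area use
$L_{sun} = 2\cos\theta_s (1 - e^{-0.5\,\Omega\,\mathrm{LAI}/\cos\theta_s})$
and $L_{sh} = \mathrm{LAI} - L_{sun}$. The zenith in $P_{VG}$ is the
*view* zenith (it describes what the sensor sees through the canopy),
while the zenith in $L_{sun}$ is the *solar* zenith (it describes what
the sun illuminates), following the two-leaf literature; the two roles
are easy to conflate. $L_{sun}$ is additionally capped at LAI so the
shaded part can never go negative for sparse canopies at low sun. The
canopy total is the LAI-weighted convex combination
$\rho_{tot} = (L_{sun}\rho_{sun} + L_{sh}\rho_{sh})/\mathrm{LAI}$,
always between the two components. Field LAI measured every ~7 days is
linearly interpolated to daily values (constant extrapolation at the
campaign edges).

## Flux processing

Half-hourly records pass four screens, each removal tagged with its
rule: (a) out of instrument range — implemented as a plausibility
window $|NEE| \le 3$ mg CO₂ m⁻² s⁻¹ since no numeric device range is
standard; (b) negative NEE at night; (c) within 1 h before or after a
rainfall event; (d) nighttime friction velocity below 0.13 m s⁻¹.
Night is PAR < 5 µmol m⁻² s⁻¹ (configurable). When a record fails
several rules it is tagged with the first in a–d order. Screening is
idempotent.

Screened nighttime NEE is taken as ecosystem respiration and fitted
with the Van't Hoff model $R_e = R_{e,ref}\, e^{B(T - 25°C)}$ by
untransformed Levenberg–Marquardt nonlinear least squares
(`minpack.lm`); a log-scale fit would re-weight the residuals toward
cold nights. The fit requires at least 10 nights spanning 5 °C —
below that, $B$ is unidentifiable. Daytime gaps are filled with the
mean diurnal course (same half-hour slot within ±7 days); nighttime
gaps with the fitted respiration at the record's temperature; slots
with no donors are flagged unfillable rather than erroring. GPP is
$R_e - NEE$ with nighttime GPP identically zero.

One consequence matters for the regression stage: gap-filled NEE is an
interpolation, not a measurement, and mean-diurnal filling smooths
exactly the high-GPP midday values the indices respond to. Matched
samples therefore carry GPP only for screened, measured half-hours;
filled values remain in the flux table for budgets and diurnal
summaries.

## GPP models and validation

Whole days are held out for validation (defaults: DOYs 224, 251, 271,
giving 286/39 of the 325 groups). Six linear forms are fitted — PRI,
SIF, PRI+SIF, each with hotspot and total-canopy predictors — with
in-sample R², RMSE (divisor $n$), and the regression F statistic, then
evaluated out-of-sample with R², RMSE, and
$\mathrm{RPD} = \mathrm{SD}/\mathrm{RMSE}$. SD is the sample ($n-1$)
standard deviation of the validation GPP, the chemometrics convention;
RPD·RMSE = SD holds by construction on every report. Stratified tables
report per-bin univariate R² with significance stars from the
regression F test at 0.05/0.01 (default bins: LAI <6/6–7/>7, T
<25/25–30/>30 °C, VPD <2/2–3/>3 kPa). Daily aggregation reports means
and standard errors, classing a day cloudy when its mean PAR is below
1,000 µmol m⁻² s⁻¹.

## The synthetic campaign

The generator emulates the field conditions end to end: 25 days
(DOYs 215–277, including the three validation days), 13 half-hour
groups per day (09:00–15:00), a 31 × 7 angular grid (azimuth −150° to
+150°, zenith 0° to 60°, 10° steps) repeated 7 times with 0.8° pointing
jitter for ~1,519 records per group; LAI peaking at 7.7 on DOY 224;
solar geometry from a low-precision declination/hour-angle formula at
32.43° N. Per-group physiology drives the component truths: SIF scales
with PAR and canopy closure, PRI darkens with light stress, shaded
leaves respond more weakly, and an independent lognormal/Gaussian
per-group factor decouples SIF from PRI (in the field, light-use
efficiency and xanthophyll state are not deterministic functions of
PAR and LAI; without this the two indices would be collinear and the
joint regression unidentifiable). Flux days add diurnal temperature
and VPD, Van't Hoff respiration with $R_{e,ref} = 0.22$,
$B = 0.1235$, a light-response GPP — overridden in the scan slots by
the coupled target
$\mathrm{GPP} = 6\,\mathrm{SIF}_{tot} - 5\,\mathrm{PRI}_{tot} + 0.15$
(mg CO₂ m⁻² s⁻¹ scale, chosen so flux magnitudes match the
respiration parameters) — plus configurable rainfall events, low-u*
nights (30% of night half-hours), range spikes, and missing slots.

The sunlit/shaded mixture and the kernel superposition cannot both be
exactly true of the same field, so the generator has three modes:
`twoleaf-exact` (default; the mixture is exact, the BRDF fit is an
approximation), `brdf-exact` (the converse, used to verify kernel
recovery), and `mixed` (their average, for qualitative end-to-end
checks). Every generator is a pure function of the truth object and
seed.

What passing tests show — and what they do not: recovery on this
campaign demonstrates that each inversion correctly inverts its own
forward model under the stated noise, and that the pipeline's
bookkeeping, screening, and coupling are faithful. Real canopies add
everything the generator omits: spectrally structured fluorescence
and reflectance within the retrieval bands, atmospheric variability,
hotspot broadening, row-structure azimuthal anisotropy, sensor
nonlinearity, and advection errors in the flux footprint. Results on
synthetic data bound correctness, not field accuracy.

## Problem sizes and numerical choices

The campaign-level checks generate index fields directly from the
forward models (the spectral encode/decode is exactly invertible and
verified separately on full scans), keeping a full pipeline run at
~325 × 1,519 angular records. Acceptance checks use 1,000 random
spectra for 3FLD exactness, 200 replicates for the BRDF noise-scaling
law, and 300 replicates for respiration-fit unbiasedness. Linear
solves use QR (`lm`/`lm.fit`); kernel geometry is clamped into valid
trigonometric ranges before `acos`; the no-dip degeneracy in 3FLD is
detected with a relative tolerance of 1e-9 because the outer-band
weights interpolate any linear irradiance exactly at the line center.
Angles are degrees at every interface and radians internally.

## Known limitations

- The four-component reflectance partition is collapsed into
  $P_{VG}$; the component reflectances of sunlit/shaded background
  are never separately estimated.
- The BRDF background is assumed constant within a half-hour group
  (no background term beyond $k_i$).
- Only the 3FLD retrieval is implemented; spectral-fitting methods
  (SFM) would be needed for spectrally structured fluorescence.
- The u* threshold is taken as given (0.13 m s⁻¹), not estimated.
- Daily regressions weight all days equally regardless of sample
  count.
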