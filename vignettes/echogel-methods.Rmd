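---
title: "Methods: posterior-shadow attenuation and echogenicity analysis of aerogel implants"
author: "echogel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posterior-shadow attenuation and echogenicity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echogel)
```

## The measurement problem

Aerogels — nanoporous solids with densities of 90–950 kg/m³ and Young's
moduli of 0.3–11 MPa — are candidates for biomedical implants. Because
their acoustic impedance ($Z = \rho v = \sqrt{\rho Y}$, of order
0.02–0.13 Mrayl) differs from soft tissue (≈1.6 Mrayl) by more than 90%,
they produce two strong signatures in B-mode ultrasound: a bright echo at
the implant's upper boundary and a dark *posterior shadow* beneath it.
`echogel` quantifies both:

1. **Attenuation.** The laterally averaged axial intensity profile of the
   shadow is fitted with $I(t) = I_0 e^{-\alpha t}$, giving the attenuation
   coefficient $\alpha$ (converted to dB/cm). Across scan frequencies,
   $\alpha = \alpha_0 f^{\,n}$ is fitted to calibrate the frequency
   dependence; the exponent $n$ for muscle recovered by this kind of
   image-based method is ≈0.7.
2. **Echogenicity.** The mean pixel intensity (MPI) of the implant area and
   of the shadow region is compared with the matching regions of an
   implant-free baseline image:
   $\Delta E = (\mathrm{MPI}_{\mathrm{implant}} -
   \mathrm{MPI}_{\mathrm{baseline}})/\mathrm{MPI}_{\mathrm{baseline}}
   \times 100$, classified anechoic ($\le -95\%$), hypoechoic
   ($-95 < \Delta E < -1$), isoechoic ($|\Delta E| \le 1$) or hyperechoic
   ($> 1\%$).

Closed-form material acoustics (speed of sound, impedance, tissue
mismatch, and the pore-scattering attenuation
$\alpha = \gamma s/2$ with pore density $\gamma = 4\vartheta/(\pi\varphi^2)$)
connect the image-derived quantities to mechanical and structural
properties.

## The synthetic phantom

Device images of implanted aerogels are not publicly deposited, so the
package includes a ground-truthed phantom generator
(`generate_phantom()`) that emulates the features the estimators rely on:

* a homogeneous speckled tissue background at a configurable mean level
  (default 100 of 255);
* a solid boundary-echo band (default 3 rows at level 250) at the
  implant's upper edge;
* an implant interior at
  `background_mean * (1 + implant_deltaE/100)` — the programmed contrast
  — applied *before* shadowing;
* an exponential posterior shadow below the boundary band, restricted to
  the implant's lateral extent, decaying at
  $\alpha = \alpha_0 f^{\,n}$ dB/cm converted to nepers/cm;
* unit-mean multiplicative speckle, clipping to [0, 255] and half-up
  rounding to integer 8-bit levels.

The default geometry is a 390 × 200 px scene at 0.01 cm/pixel (a 3.9 cm
depth of field, matching superficial linear-array scans), with a
1.0 × 0.4 cm implant whose boundary sits 0.5 cm deep. Defaults
`alpha0_true = 1.5` dB/(cm·MHzⁿ) and `n_true = 0.7` put the 8.5 MHz decay
at ≈6.7 dB/cm, mid-range of the bundled reference measurements
(2.4–20.8 dB/cm across materials and placements); `speckle_cv = 0.2`
reflects the residual texture of log-compressed B-mode data. The bundled
8.5 MHz attenuation table and the published implant-contrast values
parameterize the default pipeline scenarios; they are inputs, not
reproduction targets, because the original device images are unavailable.

**Speckle model.** Fully developed envelope speckle is Rayleigh
distributed, but a pure Rayleigh has a fixed coefficient of variation
(≈0.523) while device post-processing reduces the observed texture
contrast. The generator therefore uses a standardized Rayleigh field
rescaled to mean 1 and CV = `speckle_cv` — Rayleigh-shaped, tunable
dispersion, and exactly unit-mean so the decay law is unbiased. For
`speckle_cv <= 0.5` the rescaled field is strictly positive. An i.i.d.
field is used; real speckle has a lateral correlation length set by the
point-spread function, which the generator does not model (lateral
averaging over an ROI therefore reduces variance faster on phantoms than
on device images — recovery tolerances on real data should be expected to
be looser than the phantom closures below).

**What passing tests show.** Closure tests demonstrate that the
estimators are unbiased and precise *under the generator's assumptions*
(i.i.d. unit-mean multiplicative noise, ideal exponential shadow, exact
calibration). They do not validate beamforming artifacts, refraction,
reverberation, time-gain compensation or device log-compression, all of
which are deliberately out of scope.

## Numerical choices

* **Fit window.** The exponential fit starts at the profile's maximum
  within its upper 20% — the boundary peak — and runs to the profile end.
  The 20% guard prevents a bright speckle grain deep in the shadow from
  capturing the window. Depth is measured from the window start, so `I0`
  estimates the boundary intensity.
* **Initialization.** `fit_exponential()` seeds Levenberg–Marquardt
  (`minpack.lm`) with a log-linear regression; zero pixels are floored at
  1 in the log step only, and the nonlinear refinement uses the unfloored
  values. `fit_power_law()` is seeded by ordinary least squares on
  $\log\alpha \sim \log f$ (exposed as `$init` for auditability) and
  refined in linear space, where $R^2$ is also reported.
* **dB convention.** The decay model is written for intensity, so the
  default conversion is 1 np/cm = $10\log_{10}e \approx 4.3429$ dB/cm.
  Because B-mode pixels are log-compressed amplitudes, the amplitude
  convention ($20\log_{10}e$) is available everywhere via the
  `convention`/`db_convention` arguments.
* **Quantization.** Device output is 8-bit, and the generator quantizes by
  default. Quantization injects a deterministic ≈0.5-level bias that
  limits noiseless recovery to ~0.1–1% relative; the exact closed-loop
  closures (attenuation to 1e-3 relative, contrast to 1e-6 absolute) are
  therefore asserted on `quantize = FALSE` scenes, with realistic (≤1%)
  tolerances on quantized ones.
* **Degenerate inputs.** A constant profile yields `alpha = 0`,
  `r_squared = 0` and a classed warning rather than an error; a
  non-positive baseline MPI is a degenerate-baseline error; fits with
  fewer than 4 points, power laws with fewer than 3 distinct frequencies,
  and out-of-range ROIs are invalid-input errors.
* **Classification edges.** The isoechoic band is closed, $[-1, +1]$,
  forced by the ">1%" / "<−1%" convention; the anechoic cut
  $\Delta E \le -95$ operationalizes "≈−100%" and is a documented choice.
* **Seeds.** `run_pipeline()` derives one seed per generated image by
  FNV-1a hashing of (material, environment, frequency, replicate, role)
  combined with the master seed, so runs are reproducible and adding a
  scenario does not shift the random streams of existing ones.

## Replicate statistics

Replicate aggregation reports mean ± SEM (sample SD/√N, the N = 3
convention of repeated acquisitions). Echogenicity computes ΔE per
replicate pair and then averages, so the SEM is defined on the reported
statistic; with N = 3 the standardized error of the mean is Student-t
with 2 df, so "within 3 SEM" holds for ≈90% of repetitions — a property
the test suite checks at its exact rate rather than at a normal-theory
rate.

## Design decisions that were genuinely open

* **Interior shadowing.** The implant contrast is applied before the
  shadow, so strongly attenuating scenes measure an implant-area ΔE below
  the programmed value — intended physics (the wave attenuates inside the
  implant), which is why contrast closures use zero-attenuation scenes
  and the default attenuation ROI is the post-implant shadow region.
* **Reported vs derived acoustics.** For the eight bundled reference
  aerogels the published speed/impedance values are not exactly
  reproducible from their published Y and ρ via $v = \sqrt{Y/\rho}$
  (e.g. the stiffest silica gives 107 m/s by the formula against a
  published 80.6 m/s). The package always *computes* from the formula in
  `acoustic_property_table()` and ships the published measurement-derived
  values separately (`aerogel_reported_acoustics()`) for analyses where
  the published numbers are the input; the two are never mixed silently.
  Relatedly, two of the eight published per-material mismatch percentages
  are internally consistent only with a ≈1.30 Mrayl tissue reference
  rather than the stated 1.6 Mrayl; the package computes with the stated
  reference and surfaces the discrepancy instead of matching it.
* **Power-law scope.** Attenuation and power-law fits use only the
  fundamental scan frequencies (default 6.5, 7.5, 8.5, 11 MHz);
  harmonic-band images are excluded from quantitative fits because their
  pixel statistics are reshaped by device post-processing.
* **Temperature.** Carried as grouping metadata only; the generator
  encodes no temperature dependence, consistent with attenuation showing
  no strong dependence over the physiological 20–45 °C range.

## Problem sizes

The test suite and the acceptance script use 390 × 200 px phantoms (and
200 × 100 px ones where geometry is irrelevant), 50–100 seeds per
stochastic check, 200 seeds for the power-law and coverage Monte Carlos,
and 100 profiles for the fit-quality check — sizes at which every
stochastic summary (median relative error, median R², coverage rate) is
stable to well within the asserted tolerances.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- run_config(materials = aerogel_materials(),
                  out_dir = "echogel_demo", master_seed = 1)
res <- run_pipeline(cfg)
head(res$attenuation)   # material x environment x frequency records
res$power_law           # alpha0, n per material x environment
res$correlations        # Z_vs_v, Z_vs_Y, alpha_vs_* slopes
```

## Known limitations

* No segmentation or automatic implant detection: ROIs come from the
  user or from the phantom geometry.
* No spectral-shift or reference-phantom attenuation estimators; only the
  posterior-shadow intensity method.
* The phantom has no lateral speckle correlation, no device
  log-compression model, and no refraction/reverberation artifacts.
* Porosity and scattering cross-sections are user-supplied; they are not
  estimated from images.
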