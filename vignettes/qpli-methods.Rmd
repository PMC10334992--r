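---
title: "Simulating and analysing division-of-focal-plane Stokes polarimetry"
author: "qpli package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing division-of-focal-plane Stokes polarimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpli)
```

## The measurement this package models

Quantitative polarized light imaging (QPLI) infers the microstructure of
collagenous soft tissue from how the tissue changes the polarization state of
light. A circularly polarized illumination beam passes through (transmission
mode) or reflects off (reflectance mode) a birefringent sample; a
division-of-focal-plane (DoFP) polarization camera — a sensor tiled with 2x2
"superpixels" of linear micropolarizers at 0, 45, 90 and 135 degrees —
measures the linear polarization state of the emerging light in a single
shot. From the four analyzer intensities the first three Stokes parameters
are reconstructed:

$$S_0 = \tfrac{1}{2}(I_0 + I_{45} + I_{90} + I_{135}), \qquad
  S_1 = I_0 - I_{90}, \qquad S_2 = I_{45} - I_{135},$$

and from them the degree of linear polarization
$DoLP = \sqrt{S_1^2+S_2^2}/S_0$ and angle of polarization
$AoP = \tfrac{1}{2}\,\mathrm{atan2}(S_2, S_1)$. For fibrous tissue under
circular illumination, DoLP acts as a proxy for the *strength* of collagen
fiber alignment and AoP for the fiber *orientation*. ROI-level outcomes are
the mean DoLP (AVG DoLP) and the dispersion of AoP (STD AoP).

The package provides (i) a Mueller-calculus forward model of both imaging
modes, (ii) a synthetic phantom and sensor simulator, (iii) the
mosaic-to-Stokes processing chain, (iv) ROI outcome statistics with
branch-cut-safe axial circular estimators, and (v) an independent
fiber-orientation quantification for grayscale texture images (FFT angular
power plus axial von Mises fit). The goal is a tested, reproducible account
of the mode-comparison phenomenology: reflectance reduces DoLP uniformly,
and flipping either the imaging mode or the illumination handedness shifts
AoP by 90 degrees.

## Forward model

Light states are 4-component Stokes vectors $(S_0, S_1, S_2, S_3)$; optical
elements are 4x4 Mueller matrices composed in optical order
(`make_element()`, `mode_chain()`, `propagate()`). Five element kinds cover
the simulated system: linear retarders (birefringent collagen), ideal linear
polarizers, diagonal depolarizers $\mathrm{diag}(1, d_\ell, d_\ell, d_c)$,
neutral attenuators, and the helicity-flipping mirror
$\mathrm{diag}(1, 1, -1, -1)$ that represents reflection off the sample:
circularly polarized photons reverse handedness when reflected, not when
transmitted.

A single closed-form calculation explains the headline phenomenon. For
right-circular input ($S_3 = +1$) behind a retarder with fast axis $\theta$
and retardance $\delta \in (0, \pi)$, the output linear components are
$(S_1, S_2) = (-\sin 2\theta, \cos 2\theta)\sin\delta$, so
$AoP = \theta + 45^\circ$. Prepending the mirror (or switching to
left-circular input) flips the sign of $S_3$ and hence of both $S_1$ and
$S_2$, rotating AoP by exactly 90 degrees while leaving DoLP
($= |\sin\delta|$) untouched. The property tests sweep this over fast axes
and retardances; the acceptance script reproduces it through the full
image-formation pipeline.

Design choices where the physical geometry was open:

* **Reflectance is a single-pass chain** (mirror, then retarder, then
  depolarizer), not an explicit double pass through the slab. The simple
  chain already produces the observed 90-degree AoP shift and a uniform
  DoLP reduction; a double-pass variant can be expressed with
  `mode_chain()` directly (two retarder elements around the mirror) and
  serialized through `chain_to_config()`.
* **Oblique incidence is not modelled geometrically.** Reflectance-mode
  illumination in real rigs arrives some tens of degrees off normal; here
  reflectance is normal-incidence with an effective depolarization factor,
  because none of the simulated comparisons depend on the incidence angle.
* **The reflectance DoLP reduction is attributed entirely to
  depolarization** (multiple scattering of backscattered photons), not to
  diattenuation. The data this models cannot distinguish the two: both
  scale $(S_1, S_2)$ uniformly. The depolarizer keeps separate linear and
  circular factors, equal by default.
* **Conventions.** AoP and fast axes are degrees in $[-90, 90)$,
  counterclockwise from the camera horizontal; retardance is radians in
  $[0, 2\pi)$; $S_3 > 0$ is right-handed.

## The synthetic phantom generator

`generate_scene()` builds per-pixel optical property maps emulating tunable
collagen gel phantoms in a factorial design; its defaults are the simulated
study conditions and are not tuned per experiment.

* **Alignment.** Fiber axes are axial von Mises draws with concentration
  $\kappa = 4$ (aligned) or $\kappa = 0.05$ (near-uniform, disorganized).
  The same $\kappa$ also models *sub-resolution* fibril dispersion: a pixel
  containing incoherently mixed fibril orientations retains only
  $R_2(\kappa) = I_1(\kappa)/I_0(\kappa)$ of its linear polarization, which
  the generator folds into the depolarization map. This is what makes
  disorganized phantoms *darker* in DoLP (aligned $R_2(4) \approx 0.86$ vs
  disorganized $R_2(0.05) \approx 0.025$) rather than merely noisier in
  AoP.
* **Collagen density** (1.5, 3.0, 4.5 mg/mL) sets retardance
  $\delta = c_{ret} \cdot \rho \cdot t$ with $c_{ret} = 0.7$ rad/(mg/mL)
  and unit thickness factor, chosen once so that the control aligned
  transmission scene lands at AVG DoLP $\approx 0.73$ — the regime of real
  aligned gels — while the 3.0 and 4.5 mg/mL levels remain distinguishable.
  Because DoLP $\propto |\sin\delta|$, retardances past $\pi/2$ fold back;
  with these constants the 4.5 mg/mL level ($\delta \approx 3.15$) is past
  the fold, so density *orderings* of absolute DoLP are not asserted —
  the real system's thickness-to-retardance constants are unknown and only
  invariances and mode/alignment orderings are claimed. Density also adds a
  mild depolarization (3% per mg/mL above control; more scatterers).
* **Crosslinking** (riboflavin 0/0.5/1.0 mM) multiplies retardance by
  $1 + 0.2\,\mathrm{mM}$. Measured transmission-mode DoLP rises with
  crosslinking in gels, so the effect is placed on the polarizing
  (retardance) side rather than on depolarization.
* **Absorber** levels are expressed by their Beer-Lambert outcome: the
  transmissivity map is the control value (0.9) times the transmission
  level (1.0, 0.67 or 0.33). An absorber attenuates all Stokes components
  equally, so in this noise-free model it changes signal level, not DoLP;
  its realistic effect enters through shot noise at lower signal.
* **Mode.** Reflectance multiplies the depolarization retention by 0.36 —
  the uniform scaling regime observed when comparing reflectance with
  transmission DoLP maps of identical samples.
* **Spatial structure.** Random fields are drawn at superpixel (half)
  resolution and replicated 2x2: each 2x2 analyzer block then samples one
  physical patch, which models a fibril correlation length at the analyzer
  pitch and makes the noise-free round trip exact at superpixel centers.
  Scenes with per-(full-resolution-)pixel variation can be assembled by
  hand if sub-superpixel aliasing is the object of study.

`render_mosaic()` samples each pixel's output Stokes state with Malus's law
at the pixel's analyzer angle,
$I(\theta_a) = \tfrac{1}{2}(S_0 + S_1\cos 2\theta_a + S_2\sin 2\theta_a)$,
using the superpixel layout (default `[[90, 45], [135, 0]]`, row-major,
configurable — commercial sensors do not all share one layout). Noise is
Poisson shot noise at a full-scale signal of `gain` photoelectron
equivalents (default 1000) plus Gaussian read noise (default 0.5% of full
scale), digitized to 16 bits. Every stochastic operation takes an explicit
seed; there is no hidden global RNG state.

## Processing chain

`demosaic()` offers direct superpixel extraction (quarter resolution,
exact) and bilinear per-channel interpolation to full resolution (each
channel's missing pixels are interpolated from its own subgrid; borders
replicate). Intensities are interpolated first and Stokes parameters
computed afterwards; $S_0$ uses all four channels. There is no gain or
extinction-ratio calibration step, matching how modern DoFP sensors are
commonly used. Pixels with $S_0$ below $10^{-3}$ of the image maximum are
masked invalid rather than propagating NaNs; DoLP is clipped to $[0,1]$
(noise can push the raw ratio above 1).

A known estimator property worth remembering when interpreting low-signal
(reflectance) data: DoLP is a norm of noisy components, so its estimate is
biased upward where true DoLP is near zero. The test suite asserts the sign
of this bias; it is one reason disorganized-sample outcomes are less
trustworthy in dim conditions.

## ROI statistics on axial data

AoP is axial: $-89^\circ$ and $+89^\circ$ are two degrees apart. A naive
standard deviation across the $\pm 90$ branch cut is meaningless, so
`std_aop()` defaults to a *recentred* estimator: find the axial circular
mean axis from the doubled-angle resultant, map all values into the
180-degree window centred there, and take the population SD. For
concentrated data this equals the naive SD (reported STD AoP magnitudes up
to tens of degrees are consistent with a linear SD on axial data), while
remaining branch-cut safe; for `{89, -89}` it gives exactly 1 degree, and
for uniform axial data $180/\sqrt{12} \approx 51.96$ degrees. The circular
estimator $\sigma = \tfrac{1}{2}\sqrt{-2\ln R_2}$ is provided alongside for
auditability; the two agree within 1% for concentrated samples. Population
(divide-by-n) normalization is fixed for reproducibility; ROIs have
thousands of pixels, so the distinction is immaterial.

`render_map()` reproduces the two standard visualizations: a sequential
DoLP lookup table whose saturation point `scale_max` can be rescaled (a
reflectance map rendered on $[0, 0.25]$ matches its transmission
counterpart rendered on $[0, 1]$ exactly when the reduction is a uniform
0.25 scaling), and a 180-degree-periodic hue map for AoP so that $\pm 90$
degrees render identically.

## Fiber-orientation quantification

Independently of polarimetry, fiber organization can be quantified from
grayscale texture images (e.g. structural imaging slices).
`generate_fiber_texture()` renders Gaussian-profile line segments with
axial von Mises orientations (Best-Fisher sampler) as ground truth;
`ced_filter()` applies coherence-enhancing diffusion (structure-tensor
driven, Weickert-style eigenvalues
$\lambda_1 = \alpha$, $\lambda_2 = \alpha + (1-\alpha)e^{-C/(\mu_1-\mu_2)^2}$,
explicit stepping with Neumann boundaries and the $\mathrm{step} \le 0.25$
stability bound); `orientation_distribution_fft()` converts windowed 2-D
spectral power into an angular distribution (fiber angle = spectral angle
+ 90 degrees); `fit_von_mises()` fits
$p(\theta) \propto \exp(k \cos 2(\theta - \mu))$ by Levenberg-Marquardt
least squares initialized from doubled-angle moments.

Numerical choices:

* **CED defaults** `sigma_grad = 1`, `rho = 4`, `alpha = 0.001`, `C = 1`,
  `step = 0.15`, `n_iter = 20`: standard magnitudes for fiber-scale
  structures a few pixels wide; the upstream literature on this filter
  gives no canonical setting.
* **Radial band 0.1–0.8 Nyquist, Hann window** by default: excludes the
  DC/illumination peak and spectral leakage from image edges. Angular
  wedges use *count-normalized* (mean) power — discrete wedge pixel counts
  vary by a few percent and summed power would imprint that variation on
  the distribution as spurious anisotropy.
* **The spread parameter** $\sigma$ is defined as the SD of the fitted
  axial von Mises density over the 180-degree window centred on $\mu$
  (numerical quadrature). This definition is finite and well behaved over
  the whole concentration range: it reaches the uniform-limit value
  $180/\sqrt{12} = 51.96^\circ$ at $k = 0$ and converges to the axial
  circular SD $\tfrac{1}{2}\sqrt{-2\ln R_2(k)}$ (which diverges at
  $k \to 0$ and is reported alongside as `sigma_circular_deg`) as $k$
  grows. A weighted sample SD of the binned distribution would be a third
  alternative; the windowed-density definition was chosen because it is a
  property of the fit alone, independent of binning.
* **Multi-slice stacks** are analysed per slice and $k$, $\sigma$ averaged
  across slices (`fiber_metrics()`).

End-to-end recovery from rendered textures (800 fibers, 196x196 pixels) is
accurate to well within 25% over $\kappa \in [0.5, 4]$ and monotone in
$\kappa$; the residual bias comes from fiber crossings and finite segment
length, which flatten the angular spectrum slightly.

## What the simulations do and do not show

The generator emulates: concentrated vs near-uniform axial orientation
fields, density/crosslinking/absorber factor structure, mode-dependent
depolarization, helicity flip on reflection, Malus-law DoFP sampling, and
Poisson-Gaussian sensor noise. It does **not** emulate: photon transport in
scattering media (no polarization-sensitive Monte Carlo; depolarization is
a lumped diagonal factor), wavelength dependence (the broadband source is
one effective channel), oblique-incidence geometry, speckle, or the
biological content of real gels. Consequently, passing tests demonstrate
the *internal consistency* of the processing chain and the *direction* of
mode and alignment effects — not quantitative DoLP levels of any real
tissue, which depend on unknown thickness-to-retardance constants. Absolute
phantom values (e.g. an aligned-transmission AVG DoLP near 0.78) are a
regime the defaults land in by construction, not a validated prediction.

## Problem sizes and determinism

The shipped tests and the acceptance script run phantom scenes of 32–64
pixels square and textures up to 256 pixels square — sizes at which every
assertion is exercised on a single CPU in seconds while leaving the
estimators comfortably in their asymptotic regime (a 64x64 scene already
gives 3136 ROI pixels). All randomness flows through explicit seeds;
rendering, processing and fitting are deterministic functions of their
inputs, and `run_pipeline()` outputs embed the producing configuration as
CSV header comments.

## Worked example

```{r example, eval = FALSE}
sc_t <- generate_scene("aligned", "transmission", shape = c(64, 64), seed = 1)
sc_r <- generate_scene("aligned", "reflectance", shape = c(64, 64), seed = 1)
st_t <- compute_stokes(demosaic(render_mosaic(sc_t, noise = FALSE), "bilinear"))
st_r <- compute_stokes(demosaic(render_mosaic(sc_r, noise = FALSE), "bilinear"))
roi <- roi_rect(c(64, 64), margin = 4)
c(avg_dolp(st_t, roi), avg_dolp(st_r, roi))        # transmission > reflectance
aop_circular_difference(axial_mean(st_t$AoP[roi]),
                        axial_mean(st_r$AoP[roi])) # ~90 degrees
```

## Known limitations

* Density–retardance folding past $\delta = \pi/2$ (above): absolute DoLP
  is not monotone in collagen density at the default constants.
* The depolarizer is diagonal; real backscattering media can exhibit
  retardance-depolarization coupling the model cannot express.
* The FFT orientation estimator needs several fibers per image and at
  least 64x64 pixels; single-fiber images are out of scope.
* STD AoP's recentred estimator assumes a meaningful mean axis; for
  exactly balanced bimodal axes it falls back to a zero-centred window
  with a warning.
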