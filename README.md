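# qpli

Simulation and analysis of division-of-focal-plane (DoFP) Stokes
polarimetry for collagenous soft tissue — quantitative polarized light
imaging (QPLI) in transmission and reflectance modes.

## What this is for

QPLI images fibrous tissue through the polarization state of light. A
circularly polarized beam passes through (transmission) or reflects off
(reflectance) a birefringent sample, and a polarization camera whose pixels
carry a repeating 2×2 mosaic of linear analyzers (0°/45°/90°/135°) measures
the emerging linear polarization in a single shot. Per superpixel,

    S0 = (I0 + I45 + I90 + I135)/2,   S1 = I0 − I90,   S2 = I45 − I135,

    DoLP = sqrt(S1² + S2²)/S0,        AoP = ½·atan2(S2, S1),

where DoLP (degree of linear polarization) tracks the *strength* of
collagen fiber alignment and AoP (angle of polarization) the fiber
*orientation*. ROI outcomes are AVG DoLP and STD AoP (an axial,
branch-cut-safe dispersion).

The package is for researchers comparing the two imaging modes, or
validating DoFP processing chains, without bench data: it provides

* a Mueller-calculus forward model (`make_element`, `mode_chain`,
  `propagate`) including the helicity-flipping mirror of reflectance
  mode — circularly polarized photons reverse handedness on reflection,
  which surfaces as a 90° AoP shift between modes;
* a synthetic phantom generator (`generate_scene`) parameterized like
  tunable collagen-gel experiments (alignment, collagen density,
  crosslinking, absorber level) and a sensor simulator (`render_mosaic`)
  with Malus-law superpixel sampling and Poisson–Gaussian noise;
* the processing chain `demosaic` (superpixel or bilinear) →
  `compute_stokes` → `avg_dolp` / `std_aop` / `render_map`;
* fiber-orientation quantification of grayscale textures:
  coherence-enhancing diffusion (`ced_filter`), FFT angular power
  (`orientation_distribution_fft`) and an axial von Mises fit
  (`fit_von_mises`) yielding the fiber concentration k and spread σ.

## Worked example

Simulate one aligned phantom in both modes, process it, and compare:

```r
library(qpli)
sc_t <- generate_scene("aligned", "transmission", shape = c(64, 64), seed = 1)
sc_r <- generate_scene("aligned", "reflectance",  shape = c(64, 64), seed = 1)
st_t <- compute_stokes(demosaic(render_mosaic(sc_t, noise = FALSE), "bilinear"))
st_r <- compute_stokes(demosaic(render_mosaic(sc_r, noise = FALSE), "bilinear"))
roi  <- roi_rect(c(64, 64), margin = 4)

round(c(t = avg_dolp(st_t, roi), r = avg_dolp(st_r, roi)), 4)
#>      t      r
#> 0.6780 0.2428
round(c(t = std_aop(st_t, roi), r = std_aop(st_r, roi)), 2)
#>     t     r
#> 10.28 10.28
aop_circular_difference(axial_mean(st_t$AoP[roi]), axial_mean(st_r$AoP[roi]))
#> [1] 90
```

Reflectance reduces AVG DoLP by a uniform factor (0.2428/0.6780 ≈ 0.36
everywhere in the map) while leaving the orientation spread unchanged, and
the mean AoP shifts by exactly 90° — the helicity flip. A disorganized
phantom from the same seed gives AVG DoLP 0.0129 and STD AoP 50.5°, the
alignment contrast in both outcomes.

Fiber-orientation quantification recovers the concentration of a rendered
texture:

```r
tx <- generate_fiber_texture(kappa = 2, mu_deg = 20, n_fibers = 800,
                             shape = c(196, 196), seed = 1)
fit_von_mises(orientation_distribution_fft(tx))
#> <von_mises_fit> k = 2.213, mu = 21.3 deg, sigma = 23.4 deg
```

A thin CLI over the same functions lives at `inst/cli/qpli.R`
(`simulate`, `process`, `report`, `fibers`, and `demo`, which runs the
full handedness-flip experiment end to end).

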