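Package: qpli
Title: Simulation and Analysis of Division-of-Focal-Plane Stokes Polarimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Mueller-calculus forward simulator and processing pipeline for
    quantitative polarized light imaging (QPLI) with division-of-focal-plane
    (DoFP) polarization cameras. Simulates transmission- and reflectance-mode
    imaging of birefringent collagen-phantom-like scenes (including the
    helicity flip of circularly polarized light on reflection), renders raw
    superpixel mosaics with Poisson-Gaussian sensor noise, demosaics them to
    Stokes parameter images with degree and angle of linear polarization
    (DoLP/AoP) maps, and computes region-of-interest outcomes (AVG DoLP,
    STD AoP) with branch-cut-safe axial circular statistics. Also provides
    fiber-orientation quantification of grayscale texture images via
    coherence-enhancing diffusion filtering, FFT angular power spectra, and
    semicircular von Mises fitting of fiber concentration and orientation
    spread.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
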