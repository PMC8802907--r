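Package: fpmicro
Title: Fourier Ptychography Microscopy Simulation, Reconstruction and
    Resolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and reconstructing Fourier ptychography
    microscopy (FPM) acquisitions at desk scale. Provides the optical
    bookkeeping of an LED-array microscope (wave vectors, numerical-aperture
    arithmetic, USAF 1951 and Rayleigh conversions, pupil construction),
    synthetic complex-valued phantoms (USAF 1951 bar targets and
    Giemsa-banded metaphase-chromosome mimics), a coherent oblique-
    illumination forward model producing per-LED low-resolution intensity
    stacks, an iterative spectrum-stitching reconstruction with embedded
    pupil function recovery, and resolving-power evaluation via bar-target
    contrast and modulation transfer function (MTF) curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
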