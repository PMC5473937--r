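Package: lsprsheet
Title: Optical Modeling and Image Simulation for Plasmonic Nanosheet
    Interface Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the excitation optics of fluorescence imaging on a
    close-packed two-dimensional gold-nanoparticle sheet and compares it
    with conventional epifluorescence, oblique-illumination and total
    internal reflection fluorescence (TIRF) microscopy.  Provides
    closed-form TIRF evanescent-field physics (critical angle,
    penetration depth, exponential intensity profile), a quasi-static
    coupled-dipole solver for the collective plasmonic near field of the
    nanoparticle sheet with tabulated Johnson & Christy gold optical
    constants, Forster (FRET) and nanometal surface energy transfer
    (NSET) rate laws with the resulting distance-dependent fluorescence
    attenuation, a synthetic generator for fluorescently labeled
    adherent-cell geometries (ventral and dorsal actin layers, stress
    fibers, focal adhesions, calibration beads), and a camera image
    formation model (Gaussian point-spread function, Poisson shot noise,
    read noise) with axial-selectivity and signal-to-background metrics.
    A small pipeline reproduces the field-profile and modality-comparison
    studies from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
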