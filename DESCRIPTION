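Package: spemod
Title: Design of 3D-Printable Passive Proton Beam Modulators for Solar
    Particle Event Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design pipeline for passive, 3D-printable beam modulators that
    convert a monoenergetic proton beam into a prescribed solar-particle-event
    (SPE) energy spectrum. Provides an analytic depth-spectra library
    (Bethe stopping power, CSDA ranges, Bohr straggling) with import of
    externally computed Monte Carlo libraries, Gaussian foam broadening of
    the spectra over depth, constrained chi-square optimization of layer
    weights by non-negative least squares on interpolated subset nodes,
    conversion of the weights into a periodic funnel cell geometry with
    clipped-circle openings and Newton radius inversion, watertight STL
    mesh export, and deterministic forward verification (Bragg-curve
    depth-dose superposition and lateral homogeneity bounds).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
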