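Package: stoct
Title: Simulation and Reconstruction Toolkit for Spatio-Temporal Optical
    Coherence Tomography (STOC-T)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and post-processing for full-field swept-source
    optical coherence tomography with spatial-phase-mask modulated illumination
    (spatio-temporal optical coherence imaging, STOC, and its volumetric
    extension STOC-T). Provides a forward model of interferometric acquisition
    through scattering phantoms with separable mirror-image and optical-crosstalk
    field components, crosstalk suppression by averaging interferograms over
    uncorrelated phase masks, coherence-matrix diagnostics (complex degree of
    coherence between linearized detector pixels) with modified-Rician intensity
    statistics, the volumetric reconstruction chain (fixed-pattern notch
    filtering, spectral FFT with Hermitian half retention, kurtosis-driven
    polynomial phase correction, split-aperture defocus estimation, and
    entropy-driven Zernike aberration correction), and closed-form design
    calculators for guided-mode counts, crosstalk attenuation, depth of field,
    and acquisition timing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
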