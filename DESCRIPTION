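Package: synchrospread
Title: Spatial Synchrony in Range Expansion from Trap-Catch Surveys
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to estimate per-transect annual spread rates of an
    invasion front from point trap-catch surveys (indicator kriging,
    isocline crossings along radial transects, boundary displacement),
    and to quantify timescale-specific spatial synchrony in spread and
    its climatic drivers with continuous Morlet wavelet methods:
    wavelet mean fields, wavelet phasor mean fields with a
    phase-randomisation significance threshold, spatial wavelet
    coherence tested against synchrony-preserving Fourier surrogates,
    and a wavelet Moran decomposition of the percentage of synchrony
    explained by a climate predictor.  A synthetic invasion-front
    generator with known ground truth supports end-to-end testing
    without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
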