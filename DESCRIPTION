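Package: timsom
Title: Time-Shared Optical Tweezer Microrheology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of time-shared optical tweezer
    microrheology (TimSOM) experiments, in which a single laser is
    alternated at 25 kHz between a driving and a static detection trap to
    measure the complex shear modulus of viscoelastic media from
    millipascals to kilopascals. Provides fractional viscoelastic model
    families (springpot, fractional Kelvin-Voigt, fractional Maxwell),
    fractional-differential-equation and hereditary-integral simulators of
    the trapped probe under the trapezoidal time-sharing waveform,
    extraction of the deviated response function from interleaved force
    signals, analytical compensation of the time-sharing artefact via the
    first-harmonic approximation, nonlinear model fitting with confidence
    intervals, and auxiliary estimators: creep compliance and its
    conversion to the frequency domain, Jeffrey's-model indentation fits,
    Stokes-drag viscosity and trap-stiffness calibration from force scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
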