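Package: fibrediff
Title: Time-Resolved Small-Angle X-Ray Fibre Diffraction Analysis of Contracting Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved small-angle X-ray fibre
    diffraction from intact skeletal muscle. Reduces 2D detector frames to
    centred, mirrored, baseline-subtracted 1D profiles; decomposes
    equatorial, meridional and layer-line reflections with constrained
    multi-Gaussian models; calibrates reciprocal space against an etched
    grating; measures sarcomere length from high-order Bragg reflections;
    assembles stimulus-aligned time courses with mass-in-beam correction
    and rest normalization; fits activation and relaxation kinetics; and
    converts lattice and intensity observables into per-filament and
    per-motor mechanics. Includes a forward simulator that renders noisy
    detector frames from ground-truth structural time courses so the whole
    chain can be validated without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    yaml,
    readr,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
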