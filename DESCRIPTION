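Package: conewhisk
Title: Conical Whisker Mechanics, Vibrations and Contact Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quasi-static and vibrational mechanics of tapered (conical)
    rodent whiskers contacting an object. Implements closed-form quasi-static
    deflection profiles and base-torque rates for fixed-whisker and
    rotating-whisker shock geometries, a spectral eigenmode solver for the
    conical Euler-Bernoulli beam under contact-pinned and free-tip boundary
    conditions (with an independent cylinder-basis Galerkin route), damped
    modal shock and free-whisking responses, quasi-static versus band-passed
    dynamic contact-detection analysis over exploratory conditions, and a
    sub-pixel whisker video-profile analysis chain operating on synthetically
    rendered high-speed frames with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    png,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
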