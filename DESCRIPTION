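Package: popdecode
Title: Dictionary Decoding of Neural Population Responses to Stimulus
    Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking what image a visual-cortical population
    encodes immediately after an abrupt stimulus transition.  Implements a
    correlation-weighted dictionary decoder for multiunit population rate
    vectors, mutual-information estimation about the current and previous
    stimulus with shuffle bias correction, a minimal linear encoding model
    (luminance convolved with a biphasic temporal response function,
    ON minus OFF), reverse-correlation kernel estimation, and an
    orientation-preference shift analysis.  A seeded synthetic multiunit
    population generator (rectified-linear rate, Poisson spiking) stands in
    for recordings, so the full pipeline runs without any data files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
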