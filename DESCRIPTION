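Package: sobptools
Title: Spread-Out Bragg Peak Synthesis and Proton Commissioning Beam Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational layer of passively scattered proton
    beam commissioning: synthetic pristine Bragg peak and lateral profile
    generation, pulse timing on a rotating range modulator wheel with
    edge-splitting and per-step fluence equalization, spread-out Bragg peak
    (SOBP) composition and non-negative least-squares weight optimization,
    stop-pulse modulation width adjustment, depth-dose and lateral-profile
    metrics (D90, proximal 95%, SOBP width, penumbra, FWHM, flatness,
    symmetry), and measured-versus-simulated comparison reports with group
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
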