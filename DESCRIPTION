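Package: denscan
Title: Rigid-Body Screening of Structure Libraries Against Cryo-EM Density
    Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate proteins for unassigned cryo-EM/cryo-ET
    density segments by exhaustive rigid-body docking. Every atomic model in
    a library is blurred to the map resolution, docked into the segment by a
    fast-Fourier-transform translational scan over a quasi-uniform rotation
    sample, and ranked by normalized cross-correlation. Includes the map
    utilities the matching protocol depends on (MRC2014 input/output,
    low-pass filtering, density cutoff, autocrop and edge guard, Fourier
    shell correlation, occupancy ratios) and a deterministic synthetic
    benchmark generator with planted ground truth, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
SystemRequirements: fftw3
Config/testthat/edition: 3
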