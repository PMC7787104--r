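Package: refltriage
Title: Triage of Merged Crystallographic Reflection Data
Version: 0.1.0
Authors@R: person("Reflection", "Triage Maintainers",
    email = "maintainers@refltriage.org", role = c("aut", "cre"))
Description: Reads merged diffraction intensities, detects and corrects
    diffraction anisotropy by maximum-likelihood scaling, detects translational
    noncrystallographic symmetry (TNCS) from the Patterson map and refines a
    TNCS expected-intensity-factor model, tests for twinning with a TNCS-aware
    Padilla-Yeates L-test, expands data to point-group subgroups when twinning
    is indicated, and records every decision as a node in a directed acyclic
    graph of hypotheses whose leaves are phasing-ready corrected datasets.
    Includes a synthetic-pathology simulator with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
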