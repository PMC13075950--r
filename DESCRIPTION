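Package: hxms
Title: Read, Write, Validate and Simulate HXMS Hydrogen/Deuterium-Exchange
    Mass Spectrometry Files
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements the HXMS v1.0 flat-file format for peptide-level
    hydrogen/deuterium-exchange mass spectrometry (HX-MS) data: a typed S4
    data model with dataset-level validation, a byte-deterministic
    fixed-width writer and a tolerant reader, the hierarchical m/z-intensity
    codec of the raw-evidence MATCH section, deuterium-uptake computation
    with zero-timepoint referencing and replicate-average fallback,
    converters from simplified vendor-export dialects (DynamX, HDX
    Workbench, HDExaminer, BioPharma Finder and a custom CSV), a seeded
    synthetic HX-MS experiment generator built on Poisson-binomial isotopic
    envelopes, and a command-line interface for converting, validating and
    inspecting HXMS files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
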