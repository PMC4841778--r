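Package: exoflux
Title: Stable-Isotope Tracer Analysis of Stroma-Driven Metabolic Reprogramming
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for 13C stable-isotope tracer experiments in cancer
    metabolism: mass isotopologue distribution (MID) normalization and
    natural-isotope-abundance correction from GC-MS fragment formulas,
    isotopologue spectral analysis (ISA) of lipogenic acetyl-CoA sources,
    reductive-carboxylation and glycolysis metrics, exosome metabolite
    cargo-contribution estimation and dosimetry, extracellular-flux
    (OCR/ECAR) bioenergetics, and an atom-mapped steady-state simulator
    that generates every input the pipeline consumes for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
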