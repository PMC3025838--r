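Package: mitosim
Title: Lifecycle-Construct Models of Mammalian Cell Growth and Division
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A framework for building large mass-action kinetic models of
    cell-biologic processes from molecule-lifecycle constructs (states and
    rates describing a molecule from synthesis to disposal) plus a
    basic-cellular-machinery construct set that accounts for amino acids,
    nucleotides, ATP, RNAs, ribosomes and RNA polymerase and so constrains
    global transcription and translation.  Ships an example model of the
    mammalian cell cycle (33 regulatory proteins and their mRNAs coupled to
    the machinery) together with a stiff-ODE simulation engine with discrete
    division events, cell-cycle phase detection, and a constrained
    generate-and-test parameter calibrator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
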