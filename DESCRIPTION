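Package: gpcoverage
Title: Decomposition of Primary-Care Coverage into Demand, Supply and
    Productivity Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse the number of patients without an assigned
    general practitioner (GP) in list-based primary-care systems. Implements
    an exact three-way decomposition of changes in unassigned patients into a
    demand effect (enrolled patients), a supply effect (GP full-time
    equivalents) and a productivity effect (patient-to-GP ratio), together
    with the supporting workforce arithmetic (full-time-equivalent weighting,
    age-weighted patient units, required additional workforce), validated
    panel input/output, regional and national aggregation, a calibrated
    synthetic panel generator for testing, and an end-to-end reporting
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
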