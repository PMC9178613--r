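Package: hydromelt
Title: Wide-Line NMR Melting-Diagram Analysis of Protein Hydration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing wide-line 1H NMR melting diagrams of frozen
    protein solutions: a piecewise (plateau / linear / quadratic) melting-curve
    model with breakpoint estimation by profiled least squares, conversion of
    mobile-water fractions to hydration measures (g water per g protein, mobile
    waters per residue, waters per protein molecule) and of temperature to the
    normalized fundamental-temperature and potential-barrier scales,
    heterogeneity statistics of the water-binding barrier distribution that
    discriminate intrinsically disordered from globular proteins, consensus
    aggregation of secondary-structure predictor tracks with DSSP 8-to-3 state
    mapping, disorder-score region calling, and seeded synthetic-data
    generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
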