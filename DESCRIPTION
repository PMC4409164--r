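Package: estuaryr
Title: Estuarine Meiofaunal Community Analysis and Environmental Driver Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking estuarine microbial-eukaryote (meiofaunal)
    community structure to its environmental drivers. Provides a
    one-dimensional sectional-averaged tidal model yielding per-station
    hydrodynamic statistics (spring tidal range, velocities, bed shear
    stress), sediment granulometry summaries (D50, D10, Wentworth size
    fractions) and salinity-range inference models; community statistics on
    OTU tables (presence/absence transform, Sorensen dissimilarity,
    group-average clustering with SIMPROF permutation tests, non-metric
    multidimensional scaling, richness tables and two-sample tests); and a
    driver-inference suite (exhaustive BIOENV subset search, Mantel tests,
    canonical correspondence analysis with collinearity filtering and
    stepwise AIC selection, and partial least squares regression with
    variable-importance-in-projection scores). A seeded synthetic-estuary
    generator with known ground truth supports end-to-end testing of the
    whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape,
    car,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
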