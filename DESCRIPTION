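Package: occufreq
Title: Occupancy Frequency Distributions of Stream Insect Metacommunities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing occupancy frequency distributions (OFDs) of
    stream insect assemblages across nested spatial extents. Provides
    trait-based dispersal-group formation (fuzzy-coded trait
    standardisation, Gower dissimilarity, Ward clustering, ANOSIM and
    multilevel pattern analysis), a nested spatial resampling scheme that
    builds annually and spatially representative samples at reach,
    subbasin, basin and regional extents, ranked species occupancy curve
    (RSOC) multimodel inference with AICc and Akaike weights classifying
    assemblages as unimodal, bimodal or random, ensemble summaries
    (mean pattern weights, evidence ratios, OFD histograms), and a
    mechanistic synthetic community generator for testing the whole
    pipeline against known regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
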