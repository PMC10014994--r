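Package: vegstruct
Title: Vegetation Community Structure, Diversity and Spatial Pattern from
    Quadrat Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quadrat-based vegetation surveys:
    Importance Value Index from relative abundance, frequency and canopy-cover
    dominance; per-quadrat Shannon diversity with a richness/equitability
    decomposition and a diversity classification; bootstrap confidence
    intervals for mean diversity with a Monte-Carlo Lilliefors normality
    check; piecewise-linear interpolation of diversity over the sampled area
    on a Delaunay triangulation; and a seedable synthetic survey generator
    with species-abundance-distribution, occupancy and cover models for
    validating every stage. Ships fixtures encoding the taxon list and the
    published structure table of a tropical deciduous forest community under
    copal-resin extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
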