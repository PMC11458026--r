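Package: plankgrid
Title: Plankton Assemblages from Optimally Gridded Point Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Defines winter zooplankton and ichthyoplankton assemblages from
    heterogeneous point surveys. Implements geostatistical selection of an
    optimal analysis grid cell size from per-taxon semivariograms (nugget
    removal versus retention of spatially structured variance), seeded
    bootstrap aggregation of station abundances onto the grid, fuzzy c-means
    clustering of Hellinger-transformed cell means with silhouette, Mantel
    and Kelly-Gardner-Sutcliffe diagnostics for the number of clusters,
    Dufrene-Legendre indicator value analysis with permutation tests and
    Benjamini-Hochberg correction, principal component summaries of
    environmental drivers, and inter-annual comparison arithmetic. A
    synthetic survey generator with known assemblage structure provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    vegan,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
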