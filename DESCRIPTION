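Package: pyroregions
Title: Delineation of Fire-Regime Regions from Month-Coded Burned-Area Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize landscape fire regimes on a regular grid
    from month-coded annual burned-area rasters. Burned pixels are merged
    into fire events by spatio-temporal contiguity rules (consecutive-month
    adjacency plus a border-to-border distance buffer), six fire-regime
    variables are computed per grid cell and multi-year period (number of
    fires, median and 99th-percentile fire size, normalized burned area,
    fire frequency and the peak of the fire season on a fire-year frame),
    and spatially contiguous fire-regime regions are delineated by
    Ward hierarchical clustering under a queen-contiguity constraint with
    BIC model selection. Climatic covariates (dry season, climatological
    water deficit, peak dry season) and anthropic covariates are related to
    the regions via random forests, correlation-matrix PCA and redundancy
    analysis with permutation tests; temporal change is quantified by
    per-cell ordinary least-squares trends with 80 percent confidence
    intervals and by projection of later periods onto the first-period
    principal component space. A synthetic-landscape simulator with planted
    regimes makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    data.table,
    cluster,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
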