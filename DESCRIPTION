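Package: forestspec
Title: Habitat Specialization of Woody Plants Across Forest Disturbance Regimes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for stem-mapped forest censuses spanning
    communities under contrasting disturbance regimes. Implements
    torus-translation tests of species-habitat association, bipartite
    network specialization (H2' and connectance), indicator species
    analysis (IndVal) with permutation nulls, multivariate dispersion
    (PCoA embedding with betadisper-style distances to centroids),
    marginal redundancy analysis of topographic covariates, importance
    values, exact sample-based species accumulation, occurrence overlap,
    and pair-correlation functions g(r) with Monte-Carlo simulation
    envelopes. A synthetic stem-map generator with controlled habitat
    preference, Thomas-process clustering, and lognormal DBH structure
    makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
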