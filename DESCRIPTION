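Package: forestconverge
Title: Reconciling Satellite-Derived and Community-Reported Forest Cover Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-classification land-cover change detection on
    classified raster time series and for reconciling the satellite evidence
    with local ecological knowledge elicited through household surveys.
    Computes land-cover transition matrices and change maps, spectral
    vegetation indices (NDVI, NDBI, NDWI, EVI), normalized forest-cover
    trajectories with linear trend classification (decline, stable,
    increase), stratified-sample thematic accuracy assessment, categorical
    survey summaries with Fisher and Kruskal-Wallis association tests, and a
    convergence-matrix classifier that grades each forest patch as full
    convergence, partial convergence, or dissonance between the two evidence
    streams. Includes a synthetic-data module that simulates clumped
    categorical landscapes under Markov transition kernels, class-conditional
    reflectance stacks, and survey tables with designed response consensus,
    so the whole pipeline is testable without restricted field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
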