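Package: phenosal
Title: Non-Destructive Image-Based Phenotyping of Halophytes Under
    Salinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reproducible pipeline for quantifying the response of the
    halophyte Salicornia europaea to NaCl treatments from plant
    silhouettes and spectrophotometric assays.  Provides a seeded
    synthetic-data generator emulating a two-population by five-treatment
    factorial design (plant images with known geometry, absorbance
    readings with known concentrations, dominant-marker band matrices
    with known population structure); silhouette morphometry (projected
    area, branch count, shoot diameter, height); box-counting fractal
    dimension with fit diagnostics; CIELab (D65) colour summaries and
    total colour difference against the salt-free control; standard-curve
    inversion and 80%-acetone pigment equations; correlation-matrix PCA
    with Kaiser retention and factorial-score distances between
    populations; two-way ANOVA with Holm-Sidak adjusted simple effects
    and compact letter displays; and Jaccard/UPGMA clustering of RAPD
    band matrices with Newick export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    png,
    tiff,
    igraph,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan
Config/testthat/edition: 3
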