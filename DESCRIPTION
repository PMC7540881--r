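Package: elnm
Title: Eco-Linguistic Niche Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-only niche modelling applied to language groups
    (eco-linguistic niche modelling). Builds aligned environmental raster
    stacks (19 bioclimatic variables derived from monthly climate plus
    terrain derivatives from a DEM), samples occurrence points from
    language-territory polygons, fits a family of deterministic
    presence-only suitability algorithms, combines them into weighted
    elitist consensus niches with fixed-sensitivity omission thresholding,
    quantifies pairwise niche overlap (Schoener's D, Hellinger's I) with
    complete-linkage clustering, identifies eco-linguistic patterns and
    their language diversity, maps family-level eco-linguistic potential
    differentials, and computes growing-season and ecological-risk grids.
    Includes a seeded synthetic-world generator with planted niches for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mgcv,
    mclust
Config/testthat/edition: 3
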