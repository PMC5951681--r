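Package: gdmscape
Title: Landscape Genomic Dissimilarity Modelling for Restoration Seed Sourcing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape genomics of widespread foundation tree
    species: genotype matrix filtering and thinning, genomic and geographic
    distances, principal coordinates analysis, Mantel tests, per-site
    diversity, pairwise Weir-Cockerham Fst, generalized dissimilarity
    modelling (GDM) with monotone I-splines and a non-negative least squares
    fitter, variable selection and site-level cross-validation, projection of
    fitted models onto environmental raster landscapes (genomic composition
    maps, genomic vulnerability under future climate scenarios, seed-source
    matching for restoration sites), and Qst-Fst comparisons for maternal
    half-sib seedling designs. A synthetic-data module generates landscapes,
    genotypes and phenotypes with known structure so every stage can be
    tested end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    vcfR,
    pracma,
    mgcv,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
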