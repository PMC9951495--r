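Package: spritemds
Title: 3D Chromosome Reconstruction from SPRITE Multi-Way Contact Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional chromosome configurations from
    SPRITE multi-way chromatin contact clusters. Maps multi-way (k-mer)
    contacts to pairwise contact matrices under under-, neutral- and
    over-weighting schemes, converts contacts to dissimilarities by a
    power-law transformation, and solves for 3D coordinates by weighted
    stress majorization (SMACOF). Reconstructions are compared by
    reflection-similarity Procrustes alignment, and the resulting
    between-structure RMSEs are related to chromosome-level features
    (multi-way contact prevalence, long-range contact prevalence, length)
    by linear regression. Includes parsing of SPRITE cluster files and
    Hi-C triplet ("RAWobserved") files, optional iterative matrix
    balancing, a cross-tabulation of cluster counts by genomic span and
    interaction degree, a sub-region contact-dominance check, and a
    synthetic-data generator with known 3D ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
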