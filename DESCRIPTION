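Package: depictRSA
Title: Representational Similarity Analysis Across Levels of Visual Abstraction
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how object representations generalize across
    levels of visual abstraction (photos, line drawings, sketches).
    Builds representational dissimilarity matrices (1 - Pearson r) from
    layerwise activation patterns, compares them across depiction types with
    Spearman rank correlations and permutation inference (Mantel test,
    correlation-difference and across-layer variation tests, sign permutation),
    performs intra- and cross-domain linear SVM decoding of superordinate
    category, estimates pairwise object similarity from triplet odd-one-out
    choices, scores labeling responses against synonym keys, embeds super-RDMs
    with raw-stress metric multidimensional scaling, and applies
    Benjamini-Hochberg FDR within configured test families. A synthetic-data
    module with planted ground truth (shared vs. depiction-specific latents)
    makes every stage verifiable by parameter recovery, and a small
    convolutional-network adapter covers image preprocessing, layerwise feature
    extraction, hierarchy-aware top-1 scoring and layer-frozen fine-tuning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    e1071,
    igraph,
    png,
    EBImage,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
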