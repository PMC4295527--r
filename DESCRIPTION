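Package: rsavp
Title: Searchlight Variation Partitioning for Hierarchical Visual Model RDMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links hierarchical visual-dictionary models of scene
    representation (HMAX and Bag-of-Visual-Words) to voxel-wise brain
    responses through representational dissimilarity matrices (RDMs).
    Implements Gabor/C1 and prototype-based C2 features, dense SIFT and
    k-means codebook histograms, Euclidean and Cityblock RDMs, searchlight
    neural RDM extraction, distance-based variation partitioning into
    unique and shared explained-variation fractions with permutation
    inference, Monte-Carlo cluster-extent correction, across-subject
    spatial chi-square consistency maps, and ROI summary tables. Includes
    a synthetic stimulus and multi-subject volume generator with planted
    ground truth so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
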