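Package: stabmbn
Title: Stable Metabolic Brain Networks via Multiple Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction of intersubject metabolic brain networks (MBNs)
    from PET SUVR tables using a multiple-sampling (bootstrap or subsample)
    ensemble scheme with representative-network selection, false discovery
    rate and edge-probability-map thresholding, an outlier-attack protocol
    for quantifying network stability (Frobenius, Hausdorff, Euclidean and
    Canberra distances over adjacency matrices and graph-feature vectors),
    group-size balancing (random undersampling and ADASYN oversampling),
    and Bhattacharyya-distance tuning of the ensemble size. Includes a
    synthetic cohort generator with block correlation structure so the
    full pipeline can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
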