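Package: embryostat
Title: Statistics for Individually Hashed Whole-Embryo Single-Cell Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cell experiments in which whole embryos are
    individually barcoded ("hashed") so that every cell can be traced back to
    the animal it came from. Provides hash-based demultiplexing with cell-level
    quality control, construction of embryo-by-cell-type composition matrices
    with per-timepoint size factors, beta-binomial regression for differential
    cell-type abundance with a modelled litter effect, gamma-GLM modelling of
    cell-count variability across embryos, frozen reference projection with
    hierarchical k-nearest-neighbour label transfer, Getis-Ord local hot/cold
    spot detection in embeddings, and pseudo-cell aggregation. A bundled
    synthetic-data generator with known ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
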