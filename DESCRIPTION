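Package: tmespat
Title: Spatial Analysis of the Tumor Microenvironment from Multiplexed
    Immunofluorescence Cell Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying tumor-immune spatial organisation from
    single-cell centroid tables produced by multiplexed immunofluorescence
    imaging. Implements a quadrat-based cell aggregation algorithm that
    delineates cell-class aggregates as polygons and intersects tumor and
    T-cell aggregates into infiltration areas, and a cell neighborhood
    analysis that records per-cell neighborhood composition and cross-type
    nearest-neighbor distances. Includes QC filtering, rule-based
    phenotyping with internal-control HLA-1 calling, per-field-of-view
    ratio metrics with correlograms and stratified group comparisons, a
    seeded synthetic-data generator with known ground truth, and an
    end-to-end pipeline with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
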