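Package: h5adkit
Title: Native H5AD (AnnData) Input/Output, Containers and Converters for
    Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reads and writes H5AD files (the HDF5-based serialization of
    AnnData objects popularized by the Python scverse ecosystem) natively in
    R, with no foreign-function interface and no Python dependency. Provides
    an in-memory AnnData container with shape validation, subsetting and
    reference semantics, a lazily materialized file-backed variant,
    bidirectional converters to SingleCellExperiment and Seurat object
    layouts with per-slot mapping control and loss reporting, an on-disk
    conformance validator, a semantic (element-wise, not byte-wise) diff
    between H5AD files, a deterministic fixture generator covering every
    supported element encoding, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    methods,
    utils,
    stats,
    rhdf5,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    SeuratObject
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
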