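Package: oricycle
Title: Cell-Cycle Chromatin Dynamics at Replication Origins from MNase-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies cell-cycle chromatin dynamics at DNA replication
    origins from paired-end MNase-seq fragment coordinates. Provides
    per-fragment-size depth equalization across time points, 2D
    bivariate-Gaussian nucleosome kernel scoring with replication
    copy-number normalization, small-fragment (<120 bp) footprint density
    with Abf1p-site calibration, Shannon-entropy quantification of
    nucleosome disorganization, and origin-level summaries (dyad calling,
    NFR width, footprint-efficiency correlation, origin-anchored entropy
    heatmaps). A synthetic-data module simulates fragment data across a
    cell-cycle time course with planted truth so every stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
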