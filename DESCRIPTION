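Package: chromhier
Title: Hierarchical Chromatin Architecture Analysis from Binned Hi-C Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of hierarchical chromatin architecture from binned
    Hi-C contact counts: library-size and ICE (iterative correction)
    normalization, observed/expected transformation, A/B compartment
    calling from the leading eigenvector of the contact correlation
    matrix with gene-density orientation, compartment-switch
    classification and switch-versus-expression testing,
    insulation-score TAD boundary detection with fixed-width boundary
    padding, HICCUPS-style donut-filter chromatin loop calling at
    multiple resolutions, and integration with histone-mark peaks and
    gene expression (enrichment, promoter statistics, TSS meta-profiles,
    mark-expression correlation, and a simple differential-expression
    test). Includes a synthetic-data generator that plants compartments,
    TAD boundaries and focal loops with known ground truth so every
    caller can be benchmarked without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
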