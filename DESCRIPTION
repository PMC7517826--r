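Package: amlscape
Title: Single-Cell Analysis of Acute Myeloid Leukemia Hierarchies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for single-cell transcriptomic studies of
    acute myeloid leukemia (AML) bone marrow. Implements quality control and
    log2(TPM/100+1) normalization for microwell-based 3' UMI data, shared
    malignant-program discovery across patients via per-patient subclustering
    and Ward module aggregation, pseudo-cell correlation networks and
    reference-atlas cell mapping, a hurdle-model differential expression test,
    mutual-information regulon inference with data-processing-inequality
    pruning and attractor transcription-factor selection, a long-read
    single-cell pipeline for mitochondrial heteroplasmy clone tracing, and
    type I/II prognosis classification from progenitor-cluster proportions.
    Ships a synthetic-data generator emulating multi-patient bone marrow
    count matrices and targeted long reads so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    S4Vectors,
    igraph,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
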