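Package: motormea
Title: MEA Network Activity and Neuromuscular Contraction Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for validating engineered neuromuscular
    co-cultures of iPSC-derived motor neurons: Butterworth bandpass
    filtering and threshold-based spike detection on multielectrode-array
    (MEA) recordings, network-burst detection from a binned population
    firing-rate histogram, maturity staging of cultures by days in vitro,
    and quantification of myotube contractile activity before and after
    alpha-bungarotoxin blockade. Includes seeded synthetic-data generators
    (noisy voltage traces with embedded spike waveforms, Poisson spike
    trains with planted network bursts, and pre/post contraction event
    series) that emit ground truth for recovery testing of every stage.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
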