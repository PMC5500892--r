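Package: apmskit
Title: Quantitative AP-MS Interactomics and Synaptic Current Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free quantification of affinity-purification mass
    spectrometry (AP-MS) experiments from peptide peak-volume tables:
    max-normalized peptide profiles, correlation-based peptide selection,
    median protein profiles, QconCAT calibration to molecular abundances,
    and spectral abundance estimates. Ratio-based (rPV) specificity
    calling against IgG, depletion and knockout controls with robust
    thresholds derived from rPV distributions, two-step (serial)
    affinity-purification partition fractions, replicate group
    comparisons, and cross-dataset correlation analysis. Also provides
    analysis of excitatory postsynaptic currents (EPSCs): peak detection,
    20-80% rise time, onset latency, mono-exponential decay fits, event
    acceptance filters, paired-pulse and AMPA/NMDA ratios, and amplitude
    summaries. Synthetic-data generators with known ground truth cover
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
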