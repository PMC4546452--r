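Package: ltpquant
Title: Quantification of Hippocampal Slice Plasticity Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and experiment-level quantification for
    extracellular field-potential recordings from hippocampal slices,
    together with dendritic-spine morphometry and fluorescence in situ
    hybridization (FISH) expression summaries. Implements fiber-volley and
    fEPSP slope measurement (maximal slope between 20% and 80% of the
    negative peak), input-output curves, paired-pulse facilitation,
    baseline-normalized long-term potentiation time courses, post-tetanic
    potentiation, high-frequency-train depolarizing-envelope areas and
    afterpositivity scaling, spine length-to-width morphometry with
    binned-subpopulation and Kolmogorov-Smirnov comparisons, and
    background-corrected percent-of-control expression statistics. A
    synthetic-data generator with known ground truth emulates the full
    experimental protocol so that every stage of the pipeline is testable
    without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    KernSmooth
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'fepsp-features.R'
    'fish.R'
    'io.R'
    'plasticity.R'
    'sim-ephys.R'
    'spines.R'
    'stats-report.R'
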