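Package: atropos
Title: Atropisomer Stability, Racemization Kinetics, VCD and Bioscreen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing axially chiral (atropisomeric)
    small molecules from desk-scale data: folding and symmetrizing
    torsional energy scans, locating stationary points and
    enantiomerization barriers, assigning class 1/2/3 axis stability,
    fitting first-order racemization time courses and Eyring activation
    parameters, projecting barrier lower bounds from non-racemization
    observations, Boltzmann-weighting conformer IR/VCD spectra, processing
    experimental VCD blocks, fitting monomer/aggregate mixture fractions,
    assigning absolute configuration by spectral similarity, summarizing
    chiral-axis dihedral occupancy from trajectory-derived time series,
    and computing NCI-60-style dose-response endpoints, mean-graph
    statistics and COMPARE-style fingerprint correlations. A synthetic
    data module generates every input the pipeline consumes with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
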