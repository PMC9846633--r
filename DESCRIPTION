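Package: ipsckit
Title: Trial-Level Analysis of Inhibitory Postsynaptic Currents from Paired Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for voltage-clamp recordings of GABAergic
    inhibitory postsynaptic currents (IPSCs) in cerebellar granule cells,
    evoked by optogenetic stimulation of single Golgi cells or by electrical
    stimulation of Golgi-cell axons. Provides per-trial charge, peak and
    synaptic-delay metrics; connectivity classification against a baseline
    charge null (Kolmogorov-Smirnov); transmission failure-rate estimation
    from the symmetry of the failure charge distribution; sliding-difference
    classification of phasic versus delayed IPSCs; bi- and mono-exponential
    decomposition of averaged IPSC decays with derived charges and weighted
    decay time constants; slow spillover charge estimation; pharmacology
    time-course analysis with baseline-normalised epoch ratios; and a
    population-statistics battery (Conover squared-ranks variance test, exact
    one-dimensional two-cluster K-means, bootstrap inertia bimodality test,
    rank-based comparisons and correlations). A synthetic sweep generator with
    full ground truth supports calibration and validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
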