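Package: synplastkit
Title: Synaptic Plasticity and Dendritic Calcium Analysis Toolkit
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis tools for spike-timing-dependent plasticity
    experiments at pyramidal-cell to basket-cell synapses: two-photon calcium
    transient quantification (dG/R) from line and frame scans, back-propagating
    action potential attenuation profiling, neuronal morphometry (SWC input and
    output, Sholl analysis, Gaussian density maps, Jarvis-march convex hulls,
    putative axo-dendritic contact detection), current-clamp electrophysiology
    metrics (spike detection, rheobase, input resistance, quality control, EPSP
    amplitude, paired-pulse ratio, coefficient-of-variation quantal analysis),
    two-photon optogenetic connection-mapping logic, random-intercept linear
    mixed models with Tukey-adjusted pairwise contrasts, and a synthetic-data
    generator with embedded ground truth used to validate the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
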