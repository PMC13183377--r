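Package: ovirhythm
Title: Circadian Rhythm Detection in Drosophila Egg-Laying Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects circadian rhythmicity in sparse, discrete, trending
    egg-count time series from semi-automated oviposition monitors. Implements
    moving-average detrending with pointwise division, population averaging,
    a from-scratch variance-normalized Lomb-Scargle periodogram with
    shuffle-based significance lines, peak detection and period estimation,
    and the strong/weak/arrhythmic classification rules used for genotype and
    individual fly calls. Ships a synthetic egg-record generator emulating the
    collection device (inhomogeneous Poisson counts with exponential trend and
    a von Mises-shaped evening peak), genotype-comparison statistics ('N-1'
    chi-squared, Cohen's d), and tools to classify synapse-count connection
    strengths and extract clock-to-oviposition bipartite connectivity from
    neuPrint-style connectome edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Collate:
    'ovirhythm-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'simulate.R'
    'io.R'
    'detrend.R'
    'periodogram.R'
    'classify.R'
    'popstats.R'
    'connectome.R'
    'network-io.R'
    'pipeline.R'
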