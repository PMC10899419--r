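Package: NeuroPixelHD
Title: Hyperdimensional Decoding of Multi-Unit Spiking Activity at
    Multiple Spatiotemporal Resolutions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements NeuroPixelHD, a hyperdimensional-computing (HDC)
    encoder and adaptively trained classifier for large-scale multi-unit
    spiking activity, together with the spatial (neuron, E/I population,
    area, region, whole brain) and temporal (1-250 ms bins) aggregation
    machinery needed to ask at which spatiotemporal resolution decoding
    accuracy is maximal. Includes Fano-factor based excitatory/inhibitory
    population clustering, trial-shuffling data augmentation, F1 and
    Euclidean-grid accuracy measures with analytic chance levels,
    Wilcoxon-based optimal-resolution selection, Welch-spectrum
    oscillation peak parameterization, permutation tests for correlation,
    and a synthetic spike-data generator emulating a 250 ms visual
    stimulation protocol (81-location Gabor grid and 118 natural scenes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
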