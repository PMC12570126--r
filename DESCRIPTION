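Package: gfsynapse
Title: Biophysical Model of the Drosophila Giant Fiber Mixed Electrochemical Synapse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-compartment Hodgkin-Huxley model of the Drosophila Giant
    Fiber to tergotrochanteral motoneuron (GF-TTMn) circuit with a mixed
    electrochemical synapse, in which the electrical coupling conductance is
    obtained from the percentage of presynaptic terminal volume occupied by
    gap-junction protein through a sigmoid map. Provides stimulus protocols
    (single suprathreshold pulses and 100 Hz trains), latency and
    following-frequency read-outs, occupancy sweeps across genotypes, a
    two-dimensional two-sample Kolmogorov-Smirnov test (quadrant statistic,
    analytic and permutation p-values) for paired physiology/anatomy
    comparisons, and a seeded generator of synthetic per-terminal datasets
    parameterized by published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
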