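Package: n2osip
Title: Source Partitioning of Pulsed Soil N2O Emissions from Isotopocules,
    Tracers, and Gene Abundances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for attributing pulsed soil nitrous oxide (N2O) emissions
    to microbial and abiotic processes. Implements static/recirculating
    chamber flux estimation with significance gating, isotopocule
    calibration and site-preference computation against USGS 51/52
    reference materials, Keeling-plot source-signature regression,
    15N-tracer atom-fraction mass balance, endmember mixing with Rayleigh
    N2O-reduction trajectories, and absolute qPCR quantification of
    nitrate-reductase gene copies. A seeded synthetic-data generator
    emulates every input the pipeline consumes, so all stages are testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
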