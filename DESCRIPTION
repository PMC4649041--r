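Package: semimetric
Title: Semi-Metric Analysis of Weighted Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of transitivity (triangle-inequality) violations in
    weighted brain functional networks. Converts proximity (correlation)
    graphs to distance graphs by the isomorphism d = 1/w - 1, computes the
    metric closure by all-pairs shortest paths, classifies every edge as
    metric or semi-metric, and summarises networks by their semi-metric
    percentage (SMP). Includes wavelet-band (MODWT) correlation
    connectivity from region-averaged BOLD time series, an anatomical
    region hierarchy with gated hierarchical group comparison, consensus
    semi-metric backbones, node-level group difference maps, and a fully
    reproducible synthetic two-group study generator with planted
    indirect-path structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
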