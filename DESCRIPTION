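Package: axisbreak
Title: Paracrine Symmetry Breaking in the Avian Marginal Zone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of BMP4 and Vg1 paracrine interactions in the
    marginal zone of the early chick blastodisc. Each cell of a one-dimensional
    ring (or of sealed arc fragments) carries extracellular BMP4 and Vg1 and two
    intracellular factors coupled through Hill-type activation and inhibition of
    perceived, neighbourhood-averaged signals. The package provides seeded
    deterministic integration with scheduled perturbations (ligand-soaked beads,
    cell-pellet grafts, factor knockdowns, embryo fragmentation), linear
    stability analysis of homogeneous states on the ring, quantitative pattern
    readouts on circular domains (domain calling, polarity index, ligand
    anticorrelation, predicted streak number and positions), synthetic circular
    expression profiles for metric validation, and a battery of in-silico
    experiments with paired controls and seed-ensemble verdicts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
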