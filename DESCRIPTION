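Package: lipidfoam
Title: Mechanics and Active Fluctuation Analysis of Lipid-Foam Prototissues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing lipid-foam tissue mimetics: construction and
    mechanics of two-dimensional foam networks of bilayer-bound compartments
    (shape index, monolayer/bilayer tension balance, three-way junction
    relaxation, T1 topological transitions), blocked fluctuation statistics of
    vertex and edge tracks with effective-temperature power-spectral-density
    fitting, an active Brownian swimmer model with the swim-pressure vertex
    displacement law and interaction-radius inversion, spatial correlation
    analysis of vertex motion, and a synthetic-data generator (Langevin vertex
    dynamics, confined swimmers, rendered two-channel micrographs) so that
    every analysis stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    minpack.lm,
    mgcv,
    stats,
    tiff,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
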