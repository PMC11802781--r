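Package: dendrocost
Title: Energy-Optimal mRNA Localisation and Molecular Copy Numbers in Neural Dendrites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Solves the coupled steady-state reaction-diffusion equations for
    mRNA, shaft protein and spine protein along a linear dendrite, attaches ATP
    costs to transcription, translation/degradation and motor-driven transport,
    and decides the energy-optimal mRNA localisation strategy (somatic vs.
    dendritic) per molecular species. Includes a three-state run-and-pause
    transport model mapped to an effective diffusion constant, a factorial
    synthetic species grid and synthetic enrichment-screen generator,
    population-level analyses (preference fractions, per-parameter preference
    panels, rank-abundance curves), enrichment-screen cross-matching statistics
    (exact Wilcoxon rank-sum, bootstrap, detection-probability rescaling), and a
    time-dependent photoactivation simulation of somatic protein integration
    into spines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
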