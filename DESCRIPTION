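Package: membranewater
Title: Dynamics of Water Confined in Stacked Phospholipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory analysis of water confined between stacked
    phospholipid bilayers at varying hydration: in-plane mean-square
    displacement and lateral diffusion coefficients, dipolar rotational
    correlation functions with model-free relaxation times and a
    constrained three-population exponential decomposition, geometric
    hydrogen-bond detection with structural statistics, intermittent
    hydrogen-bond time-correlation functions with water-water versus
    water-lipid slowdown factors, and a Voronoi-based membrane-distance
    decomposition of the interface with region-resolved dynamics.
    Includes synthetic-trajectory generators (in-plane Brownian motion,
    rotational diffusion, two-state hydrogen-bond telegraph processes,
    and a layered membrane system) with known ground truth so every
    estimator can be validated without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
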