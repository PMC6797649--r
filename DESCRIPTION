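Package: lobematch
Title: Laplacian-Based Shape Matching of Largely Deformed Lung Lobe Surfaces
Version: 0.1.0
Authors@R: person("lobematch", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Non-rigid registration of closed triangulated surfaces that
    undergo large deformations, such as lung lobes between the inflated and
    collapsed (pneumothorax) states. A fixed-topology template is deformed
    onto each target surface by iterated Laplacian-constrained quadratic
    updates driven by a progressively grown set of positional constraints,
    with the Laplacian of the cumulative displacement field smoothing the
    constraint anchors so the recovered deformation stays locally affine.
    Includes surface-distance and smoothness metrics, affine and
    piecewise-affine baselines, an SVD-based inter-subject statistical
    deformation model, a seeded synthetic lobe generator with analytic
    ground-truth displacement fields, and PLY/STL mesh input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
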