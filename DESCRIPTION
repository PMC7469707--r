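Package: edem
Title: Extended Discrete Element Analysis of Articular Joint Contact
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete element analysis of articular joint contact with rigid
    bones and an elastic-foundation (spring mattress) cartilage model. Contact
    springs are cast along triangle normals from one articular surface to the
    other, thresholded on length, and assigned strain-dependent stiffness; a
    translation-only active-set equilibrium solver with iterative release of
    tensile springs yields per-triangle contact pressures. The extended
    formulation (EDEM) tracks the cumulative translation of the moving bone
    across a gait stance phase and carries per-spring push-back forces between
    time points, while the classical formulation (DEM) keeps the bone at its
    reference pose. Includes mesh input/output (STL, OBJ, PLY), least-squares
    cylinder fitting of the joint axis, tension-only ligament bundles,
    parametric synthetic joint fixtures, stance-phase pipelines driven by joint
    angle/force time series, and a global sensitivity analysis of peak contact
    pressure over the length-threshold and ligament-modulus plane.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
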