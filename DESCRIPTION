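Package: woundloop
Title: Closed-Loop Treatment Optimization for a Spatial Wound-Healing Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates radially symmetric wound-healing dynamics (debris,
    M1/M2 macrophages, temporary and new tissue) under spatial drug dosing,
    learns a four-stage linear representation of the nonlinear dynamics with
    a neural encoder/decoder trained on a Jacobian-consistency objective
    (a Koopman-style embedding), derives an optimal dosing reference by
    linear-quadratic regulation on the learned stage model, and trains a
    deep Q-learning agent that tracks the decoded reference to minimize
    healing time. Includes policy evaluation, safety profiling and
    reproducible closed-loop training.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
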