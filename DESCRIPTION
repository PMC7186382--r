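Package: nmsarm
Title: Neuro-Musculoskeletal Simulation of Perturbed Elbow Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-dynamic simulation of goal-directed single-joint elbow
    movements with a neuro-musculoskeletal model: a one-degree-of-freedom rigid
    forearm actuated by four Hill-type muscle-tendon units with Hatze-style
    length-dependent activation dynamics and via-ellipse muscle routing. The
    controller combines an optimized triphasic (intermittent equilibrium-point)
    open-loop stimulation pattern with time-delayed proportional-derivative
    feedback on muscle fiber length and contraction velocity, emulating short-
    (25 ms) and long-latency (50 ms) stretch reflexes. Includes static
    (inertia/damping) and dynamic (torque impulse) perturbation protocols,
    evaluation statistics (early velocity, dysmetria, velocity quotient),
    internal force reporting (muscle, muscle-bone contact, joint constraint
    forces, active joint torque), and a torque-driven comparison model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
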