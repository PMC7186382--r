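geom0 <- arm_geometry(upper_arm_length = 0.31, forearm_length = 0.45,
                      forearm_mass = 1.8, forearm_com_distance = 0.18,
                      forearm_inertia_about_elbow = 0.2)

test_that("rigid-body dynamics: equilibrium, linearity, viscous sign", {
  st <- list(elbow_angle = 1, elbow_velocity = 0)
  expect_equal(equations_of_motion(st, 0, geom0), 0)
  # linear in the applied torque at fixed state
  a1 <- equations_of_motion(st, 1.3, geom0)
  a2 <- equations_of_motion(st, 2.6, geom0)
  expect_equal(a2, 2 * a1, tolerance = 1e-14)
  # extra damping decelerates a moving arm
  mv <- list(elbow_angle = 1, elbow_velocity = 2)
  pd <- perturbation("damping_delta", damping_delta = 0.30)
  expect_lt(equations_of_motion(mv, 0, geom0, pd), 0)
})

test_that("ballistic integration matches the closed form over the impulse window", {
  # constant torque tau from rest: omega(dt) = tau dt / I
  tau <- 5; dt <- 0.0375
  rhs <- function(t, y, p) list(c(y[2], equations_of_motion(y, tau, geom0)))
  out <- deSolve::lsoda(c(1, 0), c(0, dt), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(out[2, 3]), tau * dt / geom0$forearm_inertia_about_elbow,
               tolerance = 1e-8)
})

test_that("inertia-delta simulation equals a heavier baseline plant exactly", {
  pert <- perturbation("inertia_delta", inertia_delta = 0.039)
  geom_heavy <- geom0
  geom_heavy$forearm_inertia_about_elbow <-
    geom0$forearm_inertia_about_elbow + 0.039
  st <- list(elbow_angle = 0.9, elbow_velocity = 1.4)
  expect_identical(equations_of_motion(st, 2.2, geom0, pert),
                   equations_of_motion(st, 2.2, geom_heavy))
})

test_that("kinetic energy is non-increasing under pure positive damping", {
  g <- geom0
  g$intrinsic_joint_damping <- 0.4
  rhs <- function(t, y, p) list(c(y[2], equations_of_motion(y, 0, g)))
  out <- deSolve::lsoda(c(1, 3), seq(0, 1, by = 0.01), rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-11)
  ke <- 0.5 * g$forearm_inertia_about_elbow * out[, 3]^2
  expect_true(all(diff(ke) <= 1e-12))
})

test_that("configuration errors are caught", {
  expect_error(arm_geometry(0.3, 0.45, -1, 0.18, 0.1), "positive")
  pert <- perturbation("inertia_delta", inertia_delta = -0.5)
  expect_error(effective_plant(geom0, pert), "inertia")
  expect_error(perturbation("torque_impulse", impulse_magnitude = 5,
                            impulse_duration = 0), "impulse_duration")
})

test_that("only the active perturbation kind is read", {
  p <- perturbation("damping_delta", damping_delta = 0.3, inertia_delta = 9)
  expect_equal(p$inertia_delta, 0)
  expect_equal(effective_plant(geom0, p)$inertia,
               geom0$forearm_inertia_about_elbow)
})
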