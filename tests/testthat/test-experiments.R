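test_that("early velocity on constructed trajectories", {
  tt <- seq(0, 1, by = 1e-3)
  # constant 50 deg/s from the start
  expect_equal(early_velocity(fake_kinematics(tt, rep(50, length(tt)))), 50,
               tolerance = 1e-6)
  # linear ramp w(t) = 100 t deg/s: crossing at t = 0.1, value at 0.255 s
  expect_equal(early_velocity(fake_kinematics(tt, 100 * tt)), 25.5,
               tolerance = 1e-3)
  # never exceeds the threshold
  expect_error(early_velocity(fake_kinematics(tt, rep(8, length(tt)))),
               "undefined metric")
})

test_that("dysmetria on constructed trajectories", {
  tt <- seq(0, 1, by = 1e-3)
  # clean stop at the target that stays: zero dysmetria
  w1 <- ifelse(tt < 0.5, 60 * sin(pi * tt / 0.5), 0)
  expect_equal(dysmetria(fake_kinematics(tt, w1)), 0, tolerance = 0.05)
  # overshoot to 32 deg then settle back to 30 by 1 s: position at first
  # correction is ~32, final 30 -> dysmetria about -2 deg
  amp1 <- 32 - 45  # handled via phi0 = 45: rise 32 deg then return 2
  w2 <- ifelse(tt < 0.4, 32 / 0.4 * pi / 2 * sin(pi * tt / 0.4),
               ifelse(tt < 0.7, -2 / 0.3 * pi / 2 * sin(pi * (tt - 0.4) / 0.3), 0))
  d2 <- dysmetria(fake_kinematics(tt, w2))
  expect_equal(d2, -2, tolerance = 0.1)
  # monotone undershoot that stops at 28 deg and stays: dysmetria 0
  w3 <- ifelse(tt < 0.5, 28 / 0.5 * pi / 2 * sin(pi * tt / 0.5), 0)
  expect_equal(dysmetria(fake_kinematics(tt, w3)), 0, tolerance = 0.05)
  expect_error(dysmetria(fake_kinematics(seq(0, 0.5, 1e-3), rep(20, 501))),
               "span")
})

test_that("velocity quotient arithmetic on constructed ramps", {
  tt <- seq(0, 1, by = 1e-3)
  const <- fake_kinematics(tt, rep(40, length(tt)))
  expect_equal(velocity_quotient(const, onset = 0.3, dt = 0.0375), 1,
               tolerance = 1e-9)
  # velocity doubles across the window -> quotient 1/2
  dbl <- fake_kinematics(tt, ifelse(tt < 0.3, 40, 40 + 40 * pmin((tt - 0.3) / 0.0375, 1)))
  expect_equal(velocity_quotient(dbl, onset = 0.3, dt = 0.0375), 0.5,
               tolerance = 0.01)
  # velocity halves -> quotient 2
  hlf <- fake_kinematics(tt, ifelse(tt < 0.3, 40, 40 - 20 * pmin((tt - 0.3) / 0.0375, 1)))
  expect_equal(velocity_quotient(hlf, onset = 0.3, dt = 0.0375), 2,
               tolerance = 0.01)
  z <- fake_kinematics(tt, ifelse(tt < 0.3, 40, 0))
  expect_error(velocity_quotient(z, onset = 0.25, dt = 0.1), "zero velocity")
})

test_that("the perturbation-response cost matches a spreadsheet recomputation", {
  ref <- synthetic_reference_table()
  # exact match of all means -> zero cost
  sim <- data.frame(type = ref$type,
                    d_early_velocity = ref$dv0_mean,
                    d_dysmetria = ref$d_mean)
  expect_equal(cost_eq5(sim, ref), 0)
  # one early-velocity term off by exactly one maximal SD, rest exact -> 1
  sim2 <- sim
  sim2$d_early_velocity[1] <- sim2$d_early_velocity[1] + max(ref$dv0_sd)
  expect_equal(cost_eq5(sim2, ref), 1)
  # brute-force recomputation over a random table
  set.seed(42)
  ref3 <- data.frame(type = paste0("t", 1:4),
                     dv0_mean = rnorm(4), dv0_sd = runif(4, 0.5, 2),
                     d_mean = rnorm(4), d_sd = runif(4, 0.5, 2))
  sim3 <- data.frame(type = ref3$type,
                     d_early_velocity = rnorm(4), d_dysmetria = rnorm(4))
  brute <- 0
  for (k in 1:4) {
    brute <- brute +
      ((sim3$d_early_velocity[k] - ref3$dv0_mean[k]) / max(ref3$dv0_sd))^2 +
      ((sim3$d_dysmetria[k] - ref3$d_mean[k]) / max(ref3$d_sd))^2
  }
  expect_equal(cost_eq5(sim3, ref3), brute, tolerance = 1e-12)
  expect_error(cost_eq5(sim3[-2, ], ref3), "missing")
})

test_that("feedback contribution conventions on constructed signals", {
  n <- 5
  mk <- function(uo, uc) {
    structure(list(u_open = matrix(uo, n, 1), u_closed = matrix(uc, n, 1),
                   u_total = matrix(pmin(pmax(uo + uc, 0), 1), n, 1)),
              class = "sim_result")
  }
  expect_equal(feedback_contribution(mk(0.5, 0.1)), 1 / 6, tolerance = 1e-12)
  # upper clip: |0.2| against the clipped total of 1.0
  expect_equal(feedback_contribution(mk(1.0, 0.2)), 0.2, tolerance = 1e-12)
  expect_equal(feedback_contribution(mk(0.5, 0)), 0)
  # the per-muscle variant agrees on a single unclipped channel
  expect_equal(feedback_contribution(mk(0.5, 0.1), how = "per_muscle"), 1 / 6,
               tolerance = 1e-12)
})

test_that("impulse scheduling fires at the configured traversed fraction", {
  model <- test_model()
  calib <- test_calibration()
  pert <- perturbation("torque_impulse", impulse_magnitude = 5,
                       impulse_onset_fraction = 0.25,
                       impulse_duration = 0.0375)
  res <- simulate_movement(model, calib$pattern, calib$plan, pert = pert,
                           diagnostics = FALSE)
  expect_true(res$impulse$fired)
  pf <- stats::splinefun(res$time, res$phi)
  traversed <- abs(pf(res$impulse$t_on) - calib$plan$start_angle)
  expect_equal(traversed,
               0.25 * abs(calib$plan$end_angle - calib$plan$start_angle),
               tolerance = 1e-3)
  expect_equal(res$impulse$t_off - res$impulse$t_on, 0.0375,
               tolerance = 1e-9)
  # a zero-magnitude impulse leaves the trajectory identical to the reference
  z <- simulate_movement(model, calib$pattern, calib$plan,
                         pert = perturbation("torque_impulse",
                                             impulse_magnitude = 0,
                                             impulse_duration = 0.0375),
                         diagnostics = FALSE)
  expect_equal(z$phi, calib$recording$phi, tolerance = 1e-5)
  # an unreachable onset fraction warns and never fires
  expect_warning(
    nf <- simulate_movement(model, calib$pattern, calib$plan,
                            pert = perturbation("torque_impulse",
                                                impulse_magnitude = 5,
                                                impulse_onset_fraction = 3,
                                                impulse_duration = 0.0375),
                            diagnostics = FALSE),
    "never fired")
  expect_false(nf$impulse$fired)
})

test_that("static perturbed runs share the pre-perturbation trajectory (causality)", {
  model <- test_model()
  calib <- test_calibration()
  pert <- perturbation("torque_impulse", impulse_magnitude = -5,
                       impulse_onset_fraction = 0.25,
                       impulse_duration = 0.0375)
  ref <- simulate_movement(model, calib$pattern, calib$plan,
                           diagnostics = FALSE)
  imp <- simulate_movement(model, calib$pattern, calib$plan, pert = pert,
                           diagnostics = FALSE)
  pre <- imp$time < imp$impulse$t_on - 1e-9
  expect_lt(max(abs(imp$phi[pre] - ref$phi[pre])), 1e-9)
})
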