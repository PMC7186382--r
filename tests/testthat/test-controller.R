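pat0 <- triphasic_pattern(u0 = c(0.1, 0.2, 0.1, 0.2), u_acc = 0.5,
                          u_min = 0.005, u_dec = c(0.3, 0.3, 0.3, 0.3),
                          u_final = c(0.15, 0.25, 0.15, 0.25),
                          t1 = 0.3, t2 = 0.7, agonists = c(1, 3))

test_that("the triphasic pattern evaluates its branches (right-continuous)", {
  expect_equal(open_loop_u(0.05, pat0), pat0$u0)
  expect_equal(open_loop_u(0.1, pat0), c(0.5, 0.005, 0.5, 0.005))
  expect_equal(open_loop_u(0.3, pat0), pat0$u_dec)     # value of the later phase
  expect_equal(open_loop_u(0.7, pat0), pat0$u_final)
  expect_equal(open_loop_u(1e6, pat0), pat0$u_final)
})

test_that("pattern invariants are enforced", {
  expect_error(triphasic_pattern(rep(0.1, 4), 0.5, 0.005, rep(0.3, 4),
                                 rep(0.1, 4), t1 = 0.8, t2 = 0.7,
                                 agonists = 1), "t1 < t2")
  expect_error(triphasic_pattern(rep(0.1, 4), 1.5, 0.005, rep(0.3, 4),
                                 rep(0.1, 4), t1 = 0.3, t2 = 0.7,
                                 agonists = 1), "0, 1")
})

test_that("stimulation summation clips to [0, 1] and is idempotent", {
  expect_equal(total_u(0.9, 0.3), 1)
  expect_equal(total_u(0.1, -0.3), 0)
  expect_equal(total_u(0.4, 0.2), 0.6)
  a <- c(0.9, 0.1, 0.4); b <- c(0.3, -0.3, 0.2)
  expect_equal(total_u(total_u(a, b), 0), total_u(a, b))
})

test_that("the feedback law reproduces a direct substitution", {
  # 1 mm length error, zero velocity error, kp = 1, l_opt = 0.1 -> +0.01
  cfg <- feedback_config(k_p = 1, k_d = 0, delay = 0.05)
  expect_equal(closed_loop_u(0.101, 0, 0.1, 0, cfg, 0.1), 0.01)
  cfg2 <- feedback_config(k_p = 0, k_d = 0.5, delay = 0.05)
  expect_equal(closed_loop_u(0.1, 0.02, 0.1, 0, cfg2, 0.1), 0.1)
  off <- feedback_config(1, 1, 0.05, enabled = FALSE)
  expect_equal(closed_loop_u(0.2, 1, 0.1, 0, off, 0.1), 0)
})

test_that("equilibrium stimulations balance the joint and hold the posture", {
  model <- test_model()
  eq <- solve_equilibrium_stimulations(model, 50 * pi / 180, u_des = 0.1)
  expect_lt(abs(eq$torque_residual), 1e-6)
  expect_true(all(eq$u >= 0 & eq$u <= 1))
  # holding the solved stimulation keeps the arm still: |velocity| < 0.5 deg/s
  # (the movement onset is placed beyond the horizon so the holding level u0
  # applies throughout the 0.5 s window)
  plan <- movement_plan(50 * pi / 180, 50 * pi / 180 + 1e-9, onset = 0.8)
  pat <- triphasic_pattern(eq$u, eq$u[model$flexors[1]], 0.005, eq$u, eq$u,
                           t1 = 0.85, t2 = 0.9, agonists = model$flexors,
                           onset = 0.8)
  res <- simulate_movement(model, pat, plan, horizon = 0.5,
                           diagnostics = FALSE)
  expect_lt(max(abs(res$omega)) * 180 / pi, 0.5)
})

test_that("raising the co-contraction level raises every equilibrium stimulation", {
  model <- test_model()
  lo <- solve_equilibrium_stimulations(model, 55 * pi / 180, u_des = 0.08)
  hi <- solve_equilibrium_stimulations(model, 55 * pi / 180, u_des = 0.2)
  expect_true(all(hi$u > lo$u))
  expect_lt(abs(hi$torque_residual), 1e-6)
})

test_that("equilibrium solving balances a constant bias torque", {
  model <- test_model()
  eq <- solve_equilibrium_stimulations(model, 60 * pi / 180, u_des = 0.1,
                                       external_torque = -1.5)
  # the muscles generate +1.5 N m of flexion torque to cancel the bias
  arms <- vapply(seq_len(4), function(i)
    moment_arm(60 * pi / 180, model$muscles[[i]]$path), numeric(1))
  expect_equal(sum(arms * eq$force), 1.5, tolerance = 1e-6)
  expect_error(solve_equilibrium_stimulations(model, 60 * pi / 180,
                                              external_torque = -500),
               "infeasible")
})

test_that("unperturbed closed-loop replay reproduces the recording exactly", {
  calib <- test_calibration()
  model <- test_model()
  replay <- simulate_movement(model, calib$pattern, calib$plan,
                              feedback = calib$feedback,
                              reference = calib$reference)
  expect_lt(max(abs(replay$u_closed)), 1e-6)
  expect_lt(max(abs(replay$phi - calib$recording$phi)), 1e-9)
})

test_that("the recorded reference matches finite differences of its length grid", {
  calib <- test_calibration()
  ref <- calib$reference
  tt <- ref$time
  i <- seq(50, length(tt) - 50, by = 37)
  fd <- (ref$lce[i + 1, ] - ref$lce[i - 1, ]) /
    (tt[i + 1] - tt[i - 1])
  expect_lt(max(abs(fd - ref$dlce[i, ])), 2e-3 * max(abs(ref$dlce)))
})

test_that("a truncated reference is rejected", {
  calib <- test_calibration()
  model <- test_model()
  expect_error(
    simulate_movement(model, calib$pattern, calib$plan,
                      feedback = calib$feedback, reference = calib$reference,
                      horizon = 2),
    "truncated")
  expect_error(eval_reference(calib$reference, 5), "truncated")
})

test_that("feedback responds exactly one delay after a state deviation", {
  model <- test_model()
  calib <- test_calibration()
  dyn <- model$config$experiments$dynamic
  pert <- perturbation("torque_impulse", impulse_magnitude = 5,
                       impulse_onset_fraction = 0.25,
                       impulse_duration = dyn$impulse_duration)
  res <- simulate_movement(model, calib$pattern, calib$plan,
                           feedback = calib$feedback,
                           reference = calib$reference, pert = pert)
  expect_true(res$impulse$fired)
  first_nz <- res$time[which(apply(abs(res$u_closed), 1, max) > 1e-9)[1]]
  expect_equal(first_nz, res$impulse$t_on + calib$feedback$delay,
               tolerance = 2.5e-3)
  # strictly nothing before onset + delay
  pre <- res$time < res$impulse$t_on + calib$feedback$delay - 2e-3
  expect_lt(max(abs(res$u_closed[pre, ])), 1e-9)
})

test_that("zero-gain feedback reduces exactly to the open-loop controller", {
  model <- test_model()
  calib <- test_calibration()
  pert <- perturbation("inertia_delta", inertia_delta = 0.039)
  ol <- simulate_movement(model, calib$pattern, calib$plan, pert = pert)
  zg <- simulate_movement(model, calib$pattern, calib$plan,
                          feedback = feedback_config(0, 0, calib$delay),
                          reference = calib$reference, pert = pert)
  expect_equal(zg$phi, ol$phi, tolerance = 2e-5)
  expect_true(all(zg$u_closed == 0))
  expect_equal(zg$u_total, zg$u_open)
})
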