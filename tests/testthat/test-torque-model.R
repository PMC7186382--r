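test_that("the torque replay reproduces the musculoskeletal trajectory", {
  model <- test_model()
  calib <- test_calibration()
  tq <- record_net_torque(calib$recording)
  rep <- simulate_torque_model(model, tq, calib$plan)
  expect_lt(max(abs(rep$phi - calib$recording$phi)) * 180 / pi, 0.05)
})

test_that("the open-loop torque model's impulse response is purely rigid-body", {
  model <- test_model()
  calib <- test_calibration()
  tq <- record_net_torque(calib$recording)
  dyn <- model$config$experiments$dynamic
  pert <- perturbation("torque_impulse",
                       impulse_magnitude = dyn$impulse_magnitude,
                       impulse_onset_fraction = dyn$impulse_onset_fraction,
                       impulse_duration = dyn$impulse_duration)
  ref <- simulate_torque_model(model, tq, calib$plan)
  imp <- simulate_torque_model(model, tq, calib$plan, pert = pert)
  expect_true(imp$impulse$fired)
  wf_i <- stats::splinefun(imp$time, imp$omega)
  wf_r <- stats::splinefun(ref$time, ref$omega)
  dw <- wf_i(imp$impulse$t_off) - wf_r(imp$impulse$t_off)
  dw_theory <- dyn$impulse_magnitude * dyn$impulse_duration /
    model$geom$forearm_inertia_about_elbow
  expect_equal(dw, dw_theory, tolerance = 0.01)
})

test_that("delayed joint-angle feedback brings the perturbed torque model toward the target", {
  model <- test_model()
  calib <- test_calibration()
  tq <- record_net_torque(calib$recording)
  pert <- perturbation("inertia_delta", inertia_delta = 0.039)
  open <- simulate_torque_model(model, tq, calib$plan, pert = pert)
  closed <- simulate_torque_model(model, tq, calib$plan, pert = pert,
                                  feedback_on = TRUE)
  target <- calib$plan$end_angle
  expect_lt(abs(closed$phi[length(closed$phi)] - target),
            abs(open$phi[length(open$phi)] - target))
})
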