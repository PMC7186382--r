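# Shared fixtures: the default model and a small calibrated controller are
# built once per test run (simulation problem sizes are kept small: reduced
# optimizer budgets, the full 1 s trial horizon).

.fixtures <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- build_model()
  .fixtures$model
}

test_plan <- function() {
  pc <- default_config()$plan
  movement_plan(pc$start_deg * pi / 180, pc$end_deg * pi / 180,
                onset = pc$onset, duration = pc$duration)
}

# calibration without the gain-search stage, small optimizer budget
test_calibration <- function(delay = 0.05) {
  key <- paste0("calib_", delay * 1000)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- calibrate_controller(
      test_model(), delay = delay, seed = 7, calibrate_gains = FALSE,
      bo_budget = 18, bo_init = 8)
  .fixtures[[key]]
}

# a synthetic sim_result carrying only kinematics, for metric unit tests
fake_kinematics <- function(time, omega_deg, phi0_deg = 45) {
  omega <- omega_deg * pi / 180
  dt <- diff(time)
  phi <- (phi0_deg * pi / 180) + cumsum(c(0, (omega[-1] + omega[-length(omega)]) / 2 * dt))
  alpha <- c(diff(omega) / dt, 0)
  structure(list(time = time, phi = phi, omega = omega, alpha = alpha,
                 pert = perturbation("none"),
                 impulse = list(fired = FALSE, t_on = NA_real_,
                                t_off = NA_real_)),
            class = "sim_result")
}
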