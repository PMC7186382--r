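# Perturbation protocols and evaluation statistics: early velocity,
# dysmetria, velocity quotient, the normalized squared-error cost against
# experimental perturbation-response statistics, and the feedback
# contribution measure.

omega_fun <- function(res) stats::splinefun(res$time, res$omega, method = "fmm")

#' Early velocity
#'
#' The joint angular velocity 155 ms after the first time the speed exceeds
#' 10 deg/s, in deg/s (signed).
#'
#' @param res a `sim_result`
#' @return early velocity (deg/s)
#' @export
early_velocity <- function(res) {
  w <- res$omega * 180 / pi
  over <- which(abs(w) > 10)
  if (!length(over)) stop("undefined metric: velocity never exceeds 10 deg/s")
  i <- over[1]
  if (i == 1) {
    t_cross <- res$time[1]
  } else {
    # linear interpolation of the threshold crossing between samples
    w0 <- abs(w[i - 1]); w1 <- abs(w[i])
    t_cross <- res$time[i - 1] +
      (10 - w0) / (w1 - w0) * (res$time[i] - res$time[i - 1])
  }
  t_eval <- t_cross + 0.155
  if (t_eval > max(res$time)) stop("trajectory too short for early velocity")
  omega_fun(res)(t_eval) * 180 / pi
}

#' Dysmetria
#'
#' Difference between the position at trial end (t = 1 s) and the position at
#' the time of first correction, in degrees. The first correction is the
#' first time after the end of the primary deceleration where the speed drops
#' below 2 deg/s or the magnitude of the angular acceleration falls below
#' 2 deg/s^2 (searching after peak deceleration avoids the trivial zero
#' crossings of the acceleration at movement onset and at peak velocity).
#' If no first correction occurs before 1 s it is set to 1 s, the dysmetria
#' is 0 and a warning is issued.
#'
#' @param res a `sim_result`
#' @param t_end trial end (s)
#' @return dysmetria (deg)
#' @export
dysmetria <- function(res, t_end = 1) {
  if (max(res$time) + 1e-9 < t_end)
    stop("trajectory does not span the trial end")
  w <- res$omega * 180 / pi
  a <- res$alpha * 180 / pi
  i_peak <- which.max(abs(w))
  dir <- sign(w[i_peak])
  after_peak <- seq(i_peak, length(res$time))
  i_dec <- after_peak[which.max(-dir * a[after_peak])]  # peak deceleration
  search <- which(res$time > res$time[i_dec] & res$time <= t_end)
  hit <- search[abs(w[search]) < 2 | abs(a[search]) < 2]
  if (!length(hit)) {
    warning("no first-correction time before trial end; dysmetria set to 0")
    return(0)
  }
  t_fc <- res$time[hit[1]]
  pf <- stats::splinefun(res$time, res$phi, method = "fmm")
  (pf(t_end) - pf(t_fc)) * 180 / pi
}

#' Velocity quotient
#'
#' Ratio of the angular velocity at the beginning of a perturbation to the
#' angular velocity `dt` after its beginning.
#'
#' @param res a `sim_result`
#' @param onset perturbation onset time (s); defaults to the recorded impulse
#'   onset of the run
#' @param dt evaluation interval (s), e.g. the impulse duration (0.0375) or
#'   0.1
#' @return dimensionless quotient
#' @export
velocity_quotient <- function(res, onset = NULL, dt = 0.0375) {
  if (is.null(onset)) {
    if (!isTRUE(res$impulse$fired))
      stop("no impulse onset available; supply `onset`")
    onset <- res$impulse$t_on
  }
  wf <- omega_fun(res)
  w1 <- wf(onset); w2 <- wf(onset + dt)
  if (abs(w2) < 1e-10) stop("undefined metric: zero velocity at onset + dt")
  w1 / w2
}

#' Feedback contribution
#'
#' Instantaneous share of the closed-loop feedback signal in the muscle
#' stimulation, maximized over time. Two conventions are offered:
#'
#' * `"drive"` (default): at each output sample, the sum over muscles of the
#'   feedback stimulation magnitudes divided by the sum of the total
#'   (clipped) stimulations - the share of feedback in the total neural
#'   drive. This is well defined throughout a movement because the summed
#'   drive never vanishes while the arm is actively controlled.
#' * `"per_muscle"`: the maximum over time and individual muscles of
#'   `|u_closed| / max(u_total, eps)`. Note that this ratio is ill-behaved
#'   whenever a channel's total stimulation is clipped to (near) zero while
#'   its feedback component is not - e.g., an antagonist held at the minimal
#'   stimulation whose fiber shortens relative to the reference - so it can
#'   exceed 1 by orders of magnitude even for a weak, stable feedback loop.
#'
#' @param res a `sim_result` with diagnostics
#' @param how `"drive"` or `"per_muscle"`
#' @param eps guard for the denominator
#' @return fraction (may exceed 1 for `"per_muscle"`)
#' @export
feedback_contribution <- function(res, how = c("drive", "per_muscle"),
                                  eps = 1e-6) {
  how <- match.arg(how)
  if (is.null(res$u_closed)) stop("run has no stimulation diagnostics")
  if (how == "per_muscle")
    return(max(abs(res$u_closed) / pmax(res$u_total, eps)))
  max(rowSums(abs(res$u_closed)) / pmax(rowSums(res$u_total), eps))
}

#' Synthetic experimental reference table
#'
#' Means and standard deviations of the early-velocity and dysmetria
#' differences (perturbed minus reference) for the four static perturbation
#' types. The packaged table is synthetic: it encodes only the qualitative
#' response signs reported for exoskeleton perturbation experiments (inertia
#' increase: slower early movement and target overshoot; damping increase:
#' slower and undershoot; the decreases mirrored), with plausible magnitudes.
#' Supply a real table with the same columns to calibrate against data.
#'
#' @param path optional CSV path (columns `type`, `dv0_mean`, `dv0_sd`,
#'   `d_mean`, `d_sd`)
#' @return data.frame
#' @export
synthetic_reference_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "synthetic_perturbation_reference.csv",
                        package = "nmsarm")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("type", "dv0_mean", "dv0_sd", "d_mean", "d_sd")
  if (!all(need %in% names(tab)))
    stop("reference table must have columns ", paste(need, collapse = ", "))
  if (any(tab$dv0_sd <= 0) || any(tab$d_sd <= 0))
    stop("reference-table standard deviations must be positive")
  tab
}

static_perturbations <- function(config) {
  st <- config$experiments$static
  list(
    inertia_increase = perturbation("inertia_delta",
                                    inertia_delta = st$inertia_increase),
    inertia_decrease = perturbation("inertia_delta",
                                    inertia_delta = st$inertia_decrease),
    damping_increase = perturbation("damping_delta",
                                    damping_delta = st$damping_increase),
    damping_decrease = perturbation("damping_delta",
                                    damping_delta = st$damping_decrease))
}

# metrics table of the static protocol for one controller variant; a
# precomputed unperturbed run may be supplied (the unperturbed closed-loop
# trajectory is identical to the recording run by the replay identity)
static_metrics <- function(model, pattern, plan, feedback, reference,
                           ref_run = NULL, horizon = 1, rtol = 1e-5) {
  runs <- run_static_protocol_runs(model, pattern, plan, feedback, reference,
                                   horizon, rtol, ref_run = ref_run)
  metrics_from_runs(runs)
}

run_static_protocol_runs <- function(model, pattern, plan, feedback,
                                     reference, horizon, rtol,
                                     ref_run = NULL) {
  perts <- static_perturbations(model$config)
  runs <- lapply(perts, function(p)
    simulate_movement(model, pattern, plan, feedback = feedback,
                      reference = reference, pert = p, horizon = horizon,
                      rtol = rtol))
  if (is.null(ref_run))
    ref_run <- simulate_movement(model, pattern, plan, feedback = feedback,
                                 reference = reference,
                                 pert = perturbation("none"),
                                 horizon = horizon, rtol = rtol)
  c(list(reference = ref_run), runs)
}

metrics_from_runs <- function(runs) {
  ev <- vapply(runs, early_velocity, numeric(1))
  dy <- vapply(runs, dysmetria, numeric(1))
  data.frame(type = names(runs), early_velocity = ev, dysmetria = dy,
             d_early_velocity = ev - ev[["reference"]],
             d_dysmetria = dy - dy[["reference"]],
             row.names = NULL)
}

#' Run the static perturbation protocol
#'
#' Five runs with an identical calibrated controller: the unperturbed
#' reference plus the four whole-trial perturbations of the arm's inertia
#' and damping, in the horizontal plane (no bias torque). The controller is
#' not re-optimized per perturbation.
#'
#' @param model an `nms_model`
#' @param calib an `nms_calibration` (from [calibrate_controller()] with zero
#'   bias torque)
#' @param feedback_on `TRUE` for the hybrid controller, `FALSE` for the
#'   open-loop ablation (zero gains)
#' @param horizon,rtol simulation settings (defaults from the calibration)
#' @return list with `runs` (named list of `sim_result`) and `metrics`
#'   (data.frame with early velocity, dysmetria and their differences to the
#'   reference run)
#' @export
run_static_protocol <- function(model, calib, feedback_on = TRUE,
                                horizon = NULL, rtol = NULL) {
  stopifnot(inherits(calib, "nms_calibration"))
  if (is.null(horizon)) horizon <- calib$horizon
  if (is.null(rtol)) rtol <- calib$rtol
  fb <- calib$feedback
  if (!feedback_on) fb <- feedback_config(0, 0, calib$delay, enabled = FALSE)
  runs <- run_static_protocol_runs(model, calib$pattern, calib$plan, fb,
                                   calib$reference, horizon, rtol)
  list(runs = runs, metrics = metrics_from_runs(runs))
}

#' Run the dynamic torque-perturbation protocol
#'
#' A constant gravity-mimicking bias torque acts throughout; the perturbation
#' is a torque impulse in or against the movement direction, fired after a
#' fraction of the movement amplitude has been traversed. The calibration
#' must have been performed with the same bias torque.
#'
#' @param model an `nms_model`
#' @param calib an `nms_calibration` for the biased plant (flexion or
#'   extension plan)
#' @param feedback_on hybrid controller or open-loop ablation
#' @param horizon,rtol simulation settings
#' @return list with `runs` (`reference`, `impulse_positive`,
#'   `impulse_negative`) and `metrics` (velocity quotients at the impulse
#'   duration and at 100 ms, and the with/against-movement velocity ratios)
#' @export
run_dynamic_protocol <- function(model, calib, feedback_on = TRUE,
                                 horizon = NULL, rtol = NULL) {
  stopifnot(inherits(calib, "nms_calibration"))
  if (is.null(horizon)) horizon <- calib$horizon
  if (is.null(rtol)) rtol <- calib$rtol
  dyn <- model$config$experiments$dynamic
  bias <- calib$bias_torque
  fb <- calib$feedback
  if (!feedback_on) fb <- feedback_config(0, 0, calib$delay, enabled = FALSE)
  mk <- function(mag) {
    p <- perturbation("torque_impulse", impulse_magnitude = mag,
                      impulse_onset_fraction = dyn$impulse_onset_fraction,
                      impulse_duration = dyn$impulse_duration)
    p$constant_torque <- bias
    p
  }
  ref_pert <- perturbation("none"); ref_pert$constant_torque <- bias
  runs <- list(
    reference = simulate_movement(model, calib$pattern, calib$plan,
                                  feedback = fb, reference = calib$reference,
                                  pert = ref_pert, horizon = horizon,
                                  rtol = rtol),
    impulse_positive = simulate_movement(model, calib$pattern, calib$plan,
                                         feedback = fb,
                                         reference = calib$reference,
                                         pert = mk(abs(dyn$impulse_magnitude)),
                                         horizon = horizon, rtol = rtol),
    impulse_negative = simulate_movement(model, calib$pattern, calib$plan,
                                         feedback = fb,
                                         reference = calib$reference,
                                         pert = mk(-abs(dyn$impulse_magnitude)),
                                         horizon = horizon, rtol = rtol))
  qdt <- model$config$experiments$quotient_dt
  dir <- if (calib$plan$end_angle >= calib$plan$start_angle) 1 else -1
  met <- lapply(runs[-1], function(r) {
    if (!isTRUE(r$impulse$fired)) return(rep(NA_real_, 2 + length(qdt)))
    wf <- omega_fun(r)
    q <- vapply(qdt, function(d) velocity_quotient(r, dt = d), numeric(1))
    # velocity ratio across the impulse window (end over start)
    ratio <- wf(r$impulse$t_on + model$config$experiments$dynamic$impulse_duration) /
      wf(r$impulse$t_on)
    c(q, ratio, r$impulse$t_on)
  })
  metrics <- data.frame(
    type = names(runs)[-1],
    with_movement = c(dir > 0, dir < 0),
    quotient_37 = vapply(met, `[[`, numeric(1), 1),
    quotient_100 = vapply(met, `[[`, numeric(1), 2),
    velocity_ratio = vapply(met, `[[`, numeric(1), 3),
    impulse_onset = vapply(met, `[[`, numeric(1), 4),
    row.names = NULL)
  list(runs = runs, metrics = metrics)
}

#' Normalized perturbation-response cost
#'
#' Sum over the static perturbation types of the squared normalized
#' differences between simulated and experimental early-velocity and
#' dysmetria changes. Each difference is normalized by the maximal standard
#' deviation of that measure across the perturbation types.
#'
#' @param sim_metrics data.frame from [run_static_protocol()] (or
#'   `static_metrics`): needs `type`, `d_early_velocity`, `d_dysmetria` for
#'   all four perturbation types
#' @param ref_table reference table, see [synthetic_reference_table()]
#' @return scalar cost
#' @export
cost_eq5 <- function(sim_metrics, ref_table) {
  types <- ref_table$type
  if (!all(types %in% sim_metrics$type))
    stop("missing perturbation type(s): ",
         paste(setdiff(types, sim_metrics$type), collapse = ", "))
  max_sd_v <- max(ref_table$dv0_sd)
  max_sd_d <- max(ref_table$d_sd)
  total <- 0
  for (k in seq_along(types)) {
    sm <- sim_metrics[sim_metrics$type == types[k], ]
    rf <- ref_table[k, ]
    total <- total +
      ((sm$d_early_velocity - rf$dv0_mean) / max_sd_v)^2 +
      ((sm$d_dysmetria - rf$d_mean) / max_sd_d)^2
  }
  total
}
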