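# Configuration I/O, time-series serialization and the end-to-end
# reproduce-all pipeline. Angles are degrees at the file interface and
# radians internally.

# recursive overlay of user values onto the defaults; unknown keys error,
# character values in numeric slots are coerced (with validation)
merge_config <- function(default, user, path = "") {
  for (nm in names(user)) {
    here <- if (path == "") nm else paste0(path, "$", nm)
    if (!nm %in% names(default))
      stop(sprintf("unknown config key '%s'", here))
    dv <- default[[nm]]; uv <- user[[nm]]
    if (is.list(dv) && !is.null(names(dv)) && length(dv) &&
        !nm %in% c("ellipses")) {
      if (!is.list(uv))
        stop(sprintf("config key '%s' must be a mapping", here))
      default[[nm]] <- merge_config(dv, uv, here)
    } else {
      if (is.numeric(dv) && is.character(uv)) {
        coerced <- suppressWarnings(as.numeric(uv))
        if (anyNA(coerced))
          stop(sprintf("config key '%s': cannot parse '%s' as a number",
                       here, uv))
        uv <- coerced
      }
      if (is.numeric(dv) && !is.numeric(uv) && !is.null(dv))
        stop(sprintf("config key '%s' must be numeric", here))
      default[[nm]] <- uv
    }
  }
  default
}

#' Load and validate a model configuration
#'
#' Reads a YAML configuration and overlays it onto [default_config()].
#' Unknown keys and non-numeric values in numeric slots are rejected;
#' structural invariants (positive masses, stimulation bounds, ellipse axes)
#' are checked by the object constructors when the model is built.
#'
#' @param path YAML file path; `NULL` returns the defaults
#' @return validated configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  # fail fast on constructor-level invariants
  invisible(build_model(cfg))
  cfg
}

#' Write a resolved configuration
#'
#' @param config configuration list
#' @param path output YAML path
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a simulation time series to CSV
#'
#' One row per output sample: time, elbow kinematics, per-muscle open/closed/
#' total stimulations, activity, fiber state and force, and (when `model` is
#' supplied) first-ellipse contact forces, elbow constraint force components
#' and the active joint torque. A `#`-prefixed header documents the units.
#'
#' @param res a `sim_result` with diagnostics
#' @param path output file path
#' @param model optionally, the model, to add the internal-load columns
#' @param overwrite allow overwriting an existing file
#' @param loads_every internal loads are evaluated every this many samples
#' @return the path, invisibly
#' @export
write_timeseries <- function(res, path, model = NULL, overwrite = FALSE,
                             loads_every = 1) {
  if (file.exists(path) && !overwrite)
    stop("output file exists (use overwrite = TRUE): ", path)
  df <- data.frame(time = res$time,
                   elbow_angle = res$phi,
                   elbow_velocity = res$omega,
                   elbow_acceleration = res$alpha)
  addm <- function(mat, prefix) {
    if (is.null(mat)) return(invisible())
    for (i in seq_len(ncol(mat)))
      df[[paste0(prefix, "_", colnames(mat)[i])]] <<- mat[, i]
  }
  addm(res$u_open, "u_open"); addm(res$u_closed, "u_closed")
  addm(res$u_total, "u_total"); addm(res$act, "activity")
  addm(res$lce, "lce"); addm(res$dlce, "dlce"); addm(res$force, "force")
  if (!is.null(res$torque_active)) df$active_torque <- res$torque_active
  if (!is.null(model)) {
    jl <- sim_loads(model, res, every = loads_every)
    full <- function(v) stats::approx(jl$time, v, xout = res$time,
                                      rule = 2)$y
    for (i in seq_len(ncol(jl$contact_first)))
      df[[paste0("contact_force_", colnames(jl$contact_first)[i])]] <-
        full(jl$contact_first[, i])
    df$constraint_fx <- full(jl$constraint_force[, "fx"])
    df$constraint_fy <- full(jl$constraint_force[, "fy"])
    df$constraint_force <- full(jl$constraint_force[, "magnitude"])
  }
  hdr <- c(
    "# nmsarm simulation time series",
    "# units: time s | elbow_angle rad | elbow_velocity rad/s | elbow_acceleration rad/s^2",
    "# units: u_* dimensionless [0,1] | activity dimensionless | lce m | dlce m/s",
    "# units: force N | contact_force N | constraint_* N | active_torque N m",
    sprintf("# perturbation: %s | impulse fired: %s", res$pert$kind,
            res$impulse$fired))
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read back a time series written by [write_timeseries()]
#'
#' @param path CSV file path
#' @return data.frame
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run the complete simulation study
#'
#' End-to-end pipeline on one configuration: controller calibration for the
#' horizontal (static-perturbation) case, the four static perturbations with
#' hybrid and open-loop control, controller re-calibration for the
#' gravity-biased flexion and extension movements (same feedback gains and
#' co-contraction levels), the four dynamic torque-impulse perturbations with
#' both controller variants, the torque-driven comparison model, the metrics
#' table, the maximal feedback contribution across all perturbed runs, and a
#' checklist of the qualitative properties reported for this class of
#' experiments.
#'
#' @param config configuration list (see [load_config()])
#' @param seed seed for all optimization stages
#' @param delay feedback delay (s): 0.025 or 0.05
#' @param out_dir optional output directory for CSV/JSON artifacts
#' @param overwrite allow overwriting existing outputs
#' @param calibrate_gains run the gain calibration stage
#' @param bo_budget,bo_init,gain_budget optimization budgets (defaults from
#'   the config)
#' @param verbose print stage progress
#' @return a `reproduce_report` list: calibrations, protocol results, metrics
#'   data.frame, feedback-contribution summary, checklist
#' @export
reproduce_all <- function(config = default_config(), seed = 1, delay = 0.05,
                          out_dir = NULL, overwrite = FALSE,
                          calibrate_gains = TRUE, bo_budget = NULL,
                          bo_init = NULL, gain_budget = NULL,
                          verbose = TRUE) {
  t_start <- Sys.time()
  say <- function(fmt, ...) {
    if (verbose)
      message(sprintf("[%6.1f s] ", as.numeric(Sys.time() - t_start)),
              sprintf(fmt, ...))
  }
  model <- build_model(config)
  horizon <- config$experiments$horizon
  rtol <- config$solver$rtol
  dyn <- config$experiments$dynamic

  say("calibrating hybrid controller (delay %.0f ms) ...", delay * 1000)
  calib <- calibrate_controller(model, delay = delay, seed = seed,
                                calibrate_gains = calibrate_gains,
                                bo_budget = bo_budget, bo_init = bo_init,
                                gain_budget = gain_budget,
                                horizon = horizon, rtol = rtol)
  gains <- list(k_p = calib$feedback$k_p, k_d = calib$feedback$k_d)

  say("static perturbation protocol (closed loop) ...")
  stat_cl <- run_static_protocol(model, calib, feedback_on = TRUE)
  say("static perturbation protocol (open loop) ...")
  stat_ol <- run_static_protocol(model, calib, feedback_on = FALSE)

  say("re-calibrating for the gravity-biased flexion movement ...")
  calib_dyn_flex <- calibrate_controller(
    model, delay = delay, bias_torque = dyn$bias_torque,
    calibrate_gains = FALSE, gains = gains, u_des_dec = calib$u_des_dec,
    seed = seed + 1, bo_budget = bo_budget, bo_init = bo_init,
    horizon = horizon, rtol = rtol)
  pc <- config$plan
  ext_plan <- movement_plan(pc$end_deg * pi / 180, pc$start_deg * pi / 180,
                            onset = pc$onset, duration = pc$duration)
  say("re-calibrating for the gravity-biased extension movement ...")
  calib_dyn_ext <- calibrate_controller(
    model, plan = ext_plan, delay = delay, bias_torque = dyn$bias_torque,
    calibrate_gains = FALSE, gains = gains, u_des_dec = calib$u_des_dec,
    seed = seed + 2, bo_budget = bo_budget, bo_init = bo_init,
    horizon = horizon, rtol = rtol)

  say("dynamic torque-impulse protocol ...")
  dyn_flex_cl <- run_dynamic_protocol(model, calib_dyn_flex, feedback_on = TRUE)
  dyn_flex_ol <- run_dynamic_protocol(model, calib_dyn_flex, feedback_on = FALSE)
  dyn_ext_cl <- run_dynamic_protocol(model, calib_dyn_ext, feedback_on = TRUE)
  dyn_ext_ol <- run_dynamic_protocol(model, calib_dyn_ext, feedback_on = FALSE)

  say("torque-driven comparison model ...")
  tq_static <- record_net_torque(calib$recording)
  tq_flex <- record_net_torque(calib_dyn_flex$recording)
  torque_runs <- list(
    unperturbed_open = simulate_torque_model(
      model, tq_static, calib$plan, feedback_on = FALSE, horizon = horizon,
      rtol = rtol),
    inertia_increase_open = simulate_torque_model(
      model, tq_static, calib$plan,
      pert = static_perturbations(config)$inertia_increase,
      feedback_on = FALSE, horizon = horizon, rtol = rtol),
    inertia_increase_closed = simulate_torque_model(
      model, tq_static, calib$plan,
      pert = static_perturbations(config)$inertia_increase,
      feedback_on = TRUE, horizon = horizon, rtol = rtol),
    impulse_positive_open = simulate_torque_model(
      model, tq_flex, calib_dyn_flex$plan,
      pert = {
        p <- perturbation("torque_impulse",
                          impulse_magnitude = abs(dyn$impulse_magnitude),
                          impulse_onset_fraction = dyn$impulse_onset_fraction,
                          impulse_duration = dyn$impulse_duration)
        p$constant_torque <- dyn$bias_torque
        p
      },
      feedback_on = FALSE, horizon = horizon, rtol = rtol),
    unperturbed_biased_open = simulate_torque_model(
      model, tq_flex, calib_dyn_flex$plan,
      pert = perturbation("none", constant_torque = dyn$bias_torque),
      feedback_on = FALSE, horizon = horizon, rtol = rtol))

  # flat metrics table keyed by (protocol, perturbation, variant)
  tag <- function(df, protocol, variant) {
    df$protocol <- protocol; df$variant <- variant
    df
  }
  metrics <- rbind(
    tag(stat_cl$metrics, "static", "closed"),
    tag(stat_ol$metrics, "static", "open"))
  dtab <- function(dp, dirn, variant) {
    d <- dp$metrics
    d$direction <- dirn
    tag(d, "dynamic", variant)
  }
  dyn_metrics <- rbind(
    dtab(dyn_flex_cl, "flexion", "closed"),
    dtab(dyn_flex_ol, "flexion", "open"),
    dtab(dyn_ext_cl, "extension", "closed"),
    dtab(dyn_ext_ol, "extension", "open"))

  # feedback contribution across the eight perturbed closed-loop runs
  pert_runs <- c(stat_cl$runs[-1],
                 dyn_flex_cl$runs[-1], dyn_ext_cl$runs[-1])
  contributions <- vapply(pert_runs, feedback_contribution, numeric(1))
  say("max feedback contribution: %.1f %%", 100 * max(contributions))

  checklist <- build_checklist(model, config, calib, stat_cl, stat_ol,
                               dyn_flex_cl, dyn_flex_ol, torque_runs)
  say("checklist: %d / %d properties pass", sum(unlist(checklist)),
      length(checklist))

  report <- structure(list(
    seed = seed, delay = delay, config = config,
    calibration = calib,
    calibration_dynamic = list(flexion = calib_dyn_flex,
                               extension = calib_dyn_ext),
    static = list(closed = stat_cl, open = stat_ol),
    dynamic = list(flexion_closed = dyn_flex_cl, flexion_open = dyn_flex_ol,
                   extension_closed = dyn_ext_cl, extension_open = dyn_ext_ol),
    torque_runs = torque_runs,
    metrics = metrics, dynamic_metrics = dyn_metrics,
    contributions = contributions,
    max_contribution = max(contributions),
    checklist = checklist,
    elapsed_s = as.numeric(Sys.time() - t_start)),
    class = "reproduce_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wp <- function(name) file.path(out_dir, name)
    write_config(config, wp("resolved_config.yaml"))
    utils::write.csv(metrics, wp("static_metrics.csv"), row.names = FALSE)
    utils::write.csv(dyn_metrics, wp("dynamic_metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, delay = delay,
           calibration = list(u_acc = calib$pattern$u_acc,
                              t1 = calib$pattern$t1,
                              k_p = calib$feedback$k_p,
                              k_d = calib$feedback$k_d,
                              u_des_dec = calib$u_des_dec,
                              tracking_mse_deg2 = calib$objective),
           contributions = as.list(contributions),
           max_contribution = max(contributions),
           checklist = checklist),
      wp("report.json"), auto_unbox = TRUE, digits = NA)
    write_timeseries(stat_cl$runs$reference, wp("unperturbed_closed.csv"),
                     model = model, overwrite = overwrite, loads_every = 10)
    write_timeseries(stat_cl$runs$inertia_increase,
                     wp("inertia_increase_closed.csv"), model = model,
                     overwrite = overwrite, loads_every = 10)
    write_timeseries(dyn_flex_cl$runs$impulse_negative,
                     wp("flexion_impulse_negative_closed.csv"), model = model,
                     overwrite = overwrite, loads_every = 10)
  }
  report
}

# evaluate the qualitative properties of the perturbation responses
build_checklist <- function(model, config, calib, stat_cl, stat_ol,
                            dyn_cl, dyn_ol, torque_runs) {
  m_cl <- stat_cl$metrics
  row <- function(df, type) df[df$type == type, ]
  dyn <- config$experiments$dynamic
  ep_inc <- effective_plant(model$geom,
                            static_perturbations(config)$inertia_increase)

  # velocity change across the impulse window, perturbed minus reference
  dw <- function(run, ref) {
    if (!isTRUE(run$impulse$fired)) return(NA_real_)
    t1 <- run$impulse$t_off
    omega_fun(run)(t1) - omega_fun(ref)(t1)
  }
  dw_muscle <- dw(dyn_ol$runs$impulse_positive, dyn_ol$runs$reference)
  dw_torque <- dw(torque_runs$impulse_positive_open,
                  torque_runs$unperturbed_biased_open)
  dw_theory <- dyn$impulse_magnitude * dyn$impulse_duration /
    model$geom$forearm_inertia_about_elbow

  wm <- dyn_cl$metrics
  ratio_with <- wm$velocity_ratio[wm$with_movement]
  ratio_against <- wm$velocity_ratio[!wm$with_movement]

  # causality: static perturbed runs share the initial state; dynamic
  # perturbed runs match the reference before impulse onset
  imp_run <- dyn_cl$runs$impulse_negative
  pre <- imp_run$time < imp_run$impulse$t_on - 1e-9
  causality <- max(abs(imp_run$phi[pre] - dyn_cl$runs$reference$phi[pre])) <
    1e-9

  # feedback direction: against-movement impulse raises flexor stimulation
  # above the open-loop level after onset + delay
  fl <- model$flexors
  post <- imp_run$time > imp_run$impulse$t_on + calib$delay
  fb_dir <- max(rowSums(imp_run$u_total[post, fl, drop = FALSE]) -
                  rowSums(imp_run$u_open[post, fl, drop = FALSE])) > 0

  list(
    unperturbed_feedback_vanishes =
      max(abs(stat_cl$runs$reference$u_closed)) < 1e-6,
    inertia_increase_slows_early_velocity =
      row(m_cl, "inertia_increase")$d_early_velocity < 0,
    inertia_increase_overshoots =
      row(m_cl, "inertia_increase")$d_dysmetria < 0,
    inertia_decrease_raises_early_velocity =
      row(m_cl, "inertia_decrease")$d_early_velocity > 0,
    damping_relation_opposite =
      row(m_cl, "damping_increase")$d_dysmetria > 0 &&
      row(m_cl, "damping_decrease")$d_dysmetria < 0,
    torque_model_inertia_increase_undershoots =
      torque_runs$inertia_increase_open$phi[
        length(torque_runs$inertia_increase_open$phi)] <
        calib$plan$end_angle,
    impulse_with_movement_speeds_up = isTRUE(ratio_with > 1),
    impulse_against_movement_slows_down = isTRUE(ratio_against < 1),
    preflex_attenuates_impulse =
      is.finite(dw_muscle) && is.finite(dw_torque) &&
      abs(dw_muscle) < abs(dw_torque),
    torque_model_impulse_matches_rigid_body =
      is.finite(dw_torque) &&
      abs(abs(dw_torque) - abs(dw_theory) /
            (ep_inc$inertia / ep_inc$inertia)) / abs(dw_theory) < 0.01,
    causality_before_impulse = causality,
    feedback_opposes_impulse = fb_dir)
}

#' @export
print.reproduce_report <- function(x, ...) {
  cat(sprintf(
    "<reproduce_report> delay %.0f ms, seed %d | max feedback contribution %.1f %% | %d/%d checks pass | %.0f s\n",
    x$delay * 1000, x$seed, 100 * x$max_contribution,
    sum(unlist(x$checklist)), length(x$checklist), x$elapsed_s))
  invisible(x)
}

#' One-at-a-time parameter sweep
#'
#' Utility that varies a single scalar configuration entry over a set of
#' values and reports the open-loop tracking error of an otherwise fixed
#' controller, as a quick sensitivity probe.
#'
#' @param config base configuration
#' @param key character vector addressing the entry, e.g.
#'   `c("controller", "u_des_dec")`
#' @param values numeric values to try
#' @param seed seed for the calibration of the base controller
#' @param bo_budget,bo_init calibration budget
#' @return data.frame with `value` and `tracking_mse_deg2`
#' @export
param_sweep <- function(config = default_config(), key, values, seed = 1,
                        bo_budget = 20, bo_init = 8) {
  out <- data.frame(value = values, tracking_mse_deg2 = NA_real_)
  for (k in seq_along(values)) {
    cfg <- config
    cfg[[key]] <- values[k]
    model <- build_model(cfg)
    cal <- calibrate_controller(model, seed = seed, calibrate_gains = FALSE,
                                bo_budget = bo_budget, bo_init = bo_init)
    out$tracking_mse_deg2[k] <- cal$objective
  }
  out
}
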