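# Model assembly: a validated configuration list is turned into an
# `nms_model` with constructed parameter/path objects and precomputed
# routing interpolants for the simulation right-hand side.

#' Default model configuration
#'
#' A complete configuration for the four-muscle elbow model: segment and
#' inertia properties (including the exoskeleton contribution to the forearm
#' inertia), Hill/activation constants and via-ellipse routing geometry per
#' muscle, controller settings, movement plan, perturbation protocol
#' magnitudes and solver settings. The values are a documented generic
#' default set (the model is not subject-specific); every number can be
#' overridden via a YAML config file, see [load_config()].
#'
#' Coordinates: the elbow sits at the origin; segment-frame x-axes point away
#' from the elbow along the owning bone. Angles are degrees at the interface
#' and radians internally.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    arm = list(
      upper_arm_length = 0.31,
      forearm_length = 0.45,
      forearm_mass = 1.8,
      forearm_com_distance = 0.18,
      forearm_inertia_about_elbow = 0.20,
      shoulder_lock_angle_deg = 30,
      intrinsic_joint_damping = 0,
      elbow_range_deg = c(5, 165),
      see_reference_deg = 60
    ),
    muscles = list(
      elbow_flexor = list(
        params = list(f_max = 400, l_ce_opt = 0.11, see_rest_length = NA),
        path = list(
          origin = c(0.20, -0.015), insertion = c(0.042, 0.008),
          ellipses = list(
            list(segment = "upper_arm", center = c(0.000, -0.0045),
                 semi_axes = c(0.027, 0.022))))
      ),
      elbow_extensor = list(
        params = list(f_max = 465, l_ce_opt = 0.11, see_rest_length = NA),
        path = list(
          origin = c(0.22, 0.012), insertion = c(-0.025, -0.011),
          ellipses = list(
            list(segment = "forearm", center = c(0.000, -0.006),
                 semi_axes = c(0.022, 0.018))))
      ),
      biart_flexor = list(
        params = list(f_max = 300, l_ce_opt = 0.13, see_rest_length = NA),
        path = list(
          origin = c(0.30, -0.018), insertion = c(0.048, 0.009),
          ellipses = list(
            list(segment = "upper_arm", center = c(0.285, -0.002),
                 semi_axes = c(0.012, 0.012)),
            list(segment = "upper_arm", center = c(0.000, -0.005),
                 semi_axes = c(0.029, 0.023))))
      ),
      biart_extensor = list(
        params = list(f_max = 365, l_ce_opt = 0.13, see_rest_length = NA),
        path = list(
          origin = c(0.29, 0.014), insertion = c(-0.027, -0.012),
          ellipses = list(
            list(segment = "upper_arm", center = c(0.280, 0.001),
                 semi_axes = c(0.011, 0.011)),
            list(segment = "forearm", center = c(0.000, -0.0065),
                 semi_axes = c(0.0235, 0.019))))
      )
    ),
    plan = list(start_deg = 45, end_deg = 75, onset = 0.1, duration = 0.6),
    controller = list(
      t2 = 0.7,
      u_min = 0.005,
      u_des_hold = 0.1,
      u_des_dec = 0.05,
      feedback = list(k_p = 0.8, k_d = 0.03, delay = 0.05),
      optimization = list(budget = 60, init = 10,
                          u_acc_bounds = c(0.005, 1),
                          t1_frac_bounds = c(0.1, 0.75)),
      gain_search = list(k_p_bounds = c(0, 2), k_d_bounds = c(0, 0.1),
                         u_des_dec_bounds = c(0.03, 0.4), budget = 24)
    ),
    experiments = list(
      static = list(inertia_increase = 0.039, inertia_decrease = -0.032,
                    damping_increase = 0.30, damping_decrease = -0.31),
      dynamic = list(bias_torque = -1.5, impulse_magnitude = 5,
                     impulse_onset_fraction = 0.25, impulse_duration = 0.0375),
      quotient_dt = c(0.0375, 0.1),
      torque_model = list(delay = 0.1, k_p = 5, k_d = 1.2),
      horizon = 1.0
    ),
    solver = list(rtol = 1e-5, dt_out = 1e-3, routing_grid = 241)
  )
}

#' Build a simulation model from a configuration
#'
#' Constructs [arm_geometry()], per-muscle [mtu_params()] and [path_spec()]
#' objects, precomputes routing interpolants over the anatomical range and
#' classifies muscles as flexors/extensors by the sign of their mid-range
#' moment arm. SEE rest lengths left as `NA` in the config are derived so
#' that the CE sits at its optimal length, with the tendon just slack, at the
#' reference posture `see_reference_deg` (default the mid-point of the
#' studied movement), which places the fibers near their optimum over the
#' operating range.
#'
#' @param config a configuration list as returned by [default_config()] or
#'   [load_config()]
#' @return object of class `nms_model`
#' @export
build_model <- function(config = default_config()) {
  ac <- config$arm
  geom <- arm_geometry(
    upper_arm_length = ac$upper_arm_length,
    forearm_length = ac$forearm_length,
    forearm_mass = ac$forearm_mass,
    forearm_com_distance = ac$forearm_com_distance,
    forearm_inertia_about_elbow = ac$forearm_inertia_about_elbow,
    shoulder_lock_angle_deg = ac$shoulder_lock_angle_deg,
    intrinsic_joint_damping = ac$intrinsic_joint_damping,
    elbow_range = ac$elbow_range_deg * pi / 180)
  phi_mid <- mean(geom$elbow_range)
  phi_ref <- ac$see_reference_deg * pi / 180
  muscles <- list()
  for (nm in names(config$muscles)) {
    mc <- config$muscles[[nm]]
    ells <- lapply(mc$path$ellipses, function(e)
      ellipse_spec(e$segment, e$center, e$semi_axes))
    path <- path_spec(mc$path$origin, mc$path$insertion, ells, name = nm)
    pargs <- mc$params
    if (is.na(pargs$see_rest_length))
      pargs$see_rest_length <- mtu_path_length(phi_ref, path) - pargs$l_ce_opt
    params <- do.call(mtu_params, pargs)
    if (params$see_rest_length <= 0)
      stop(sprintf("muscle '%s': derived SEE rest length is non-positive", nm))
    muscles[[nm]] <- list(params = params, path = path)
  }
  grid <- seq(geom$elbow_range[1], geom$elbow_range[2],
              length.out = config$solver$routing_grid)
  Lmat <- vapply(muscles, function(m) mtu_path_length(grid, m$path),
                 numeric(length(grid)))
  Lsp <- multi_spline(grid, Lmat)
  routing <- lapply(seq_along(muscles), function(i) {
    force(i)
    list(length = function(phi) vapply(phi, function(p)
           multi_spline_eval(Lsp, p)[i], numeric(1)),
         moment_arm = function(phi) vapply(phi, function(p)
           -multi_spline_eval(Lsp, p, deriv = 1)[i], numeric(1)))
  })
  names(routing) <- names(muscles)
  arms_mid <- vapply(muscles, function(m) moment_arm(phi_mid, m$path),
                     numeric(1))
  model <- structure(list(
    geom = geom, muscles = muscles, routing = routing, Lsp = Lsp,
    muscle_names = names(muscles), n_muscles = length(muscles),
    P = muscle_param_vectors(muscles),
    flexors = which(arms_mid > 0), extensors = which(arms_mid <= 0),
    config = config), class = "nms_model")
  if (length(model$flexors) == 0 || length(model$extensors) == 0)
    stop("model needs at least one flexor and one extensor")
  model
}

#' @export
print.nms_model <- function(x, ...) {
  cat(sprintf("<nms_model> %d muscles: %s\n", x$n_muscles,
              paste(x$muscle_names, collapse = ", ")))
  cat(sprintf("  inertia %.3f kg m^2, elbow range %.0f..%.0f deg\n",
              x$geom$forearm_inertia_about_elbow,
              x$geom$elbow_range[1] * 180 / pi,
              x$geom$elbow_range[2] * 180 / pi))
  invisible(x)
}

#' Agonist muscle set for a movement direction
#'
#' Flexors are the agonists of a flexion movement (end angle above start
#' angle), extensors of an extension movement.
#'
#' @param model an `nms_model`
#' @param plan a [movement_plan()]
#' @return integer indices of the agonist muscles
#' @export
agonist_set <- function(model, plan) {
  if (plan$end_angle >= plan$start_angle) model$flexors else model$extensors
}
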