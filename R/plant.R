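# One-degree-of-freedom rigid-body dynamics of the forearm (shoulder locked),
# with static property perturbations (inertia/damping deltas), a constant
# gravity-mimicking bias torque, and scheduled torque impulses.

#' Arm geometry and rigid-body properties
#'
#' @param upper_arm_length upper arm length (m)
#' @param forearm_length forearm (+hand) length (m)
#' @param forearm_mass forearm (+hand) mass (kg)
#' @param forearm_com_distance elbow-to-center-of-mass distance (m)
#' @param forearm_inertia_about_elbow moment of inertia about the elbow axis
#'   (kg m^2), already including the exoskeleton contribution
#' @param shoulder_lock_angle_deg locked shoulder angle (degrees); fixed for a
#'   simulation run
#' @param intrinsic_joint_damping baseline viscous joint damping (N m s/rad)
#' @param elbow_range anatomical elbow range (rad, length 2); integration
#'   aborts outside it
#' @return object of class `arm_geometry`
#' @export
arm_geometry <- function(upper_arm_length, forearm_length, forearm_mass,
                         forearm_com_distance, forearm_inertia_about_elbow,
                         shoulder_lock_angle_deg = 30,
                         intrinsic_joint_damping = 0,
                         elbow_range = c(5, 165) * pi / 180) {
  if (any(c(upper_arm_length, forearm_length, forearm_mass,
            forearm_com_distance, forearm_inertia_about_elbow) <= 0))
    stop("lengths, masses and inertias must be strictly positive")
  stopifnot(length(elbow_range) == 2, elbow_range[1] < elbow_range[2])
  structure(as.list(environment()), class = "arm_geometry")
}

#' Perturbation specification
#'
#' Exactly the fields of the active kind are read; the others are ignored.
#' `inertia_delta` and `damping_delta` act for the whole trial (the robot
#' renders them continuously); `constant_torque` is a gravity-mimicking bias
#' used in the dynamic protocol; `torque_impulse` is a finite torque pulse
#' scheduled by traversed movement fraction.
#'
#' @param kind one of `"none"`, `"inertia_delta"`, `"damping_delta"`,
#'   `"torque_impulse"`
#' @param inertia_delta added moment of inertia (kg m^2; printed by robots as
#'   "kg m s^2", read here as kg m^2)
#' @param damping_delta added viscous damping (N m s/rad; may be negative,
#'   the robot's assistive behavior)
#' @param constant_torque constant bias torque (N m)
#' @param impulse_magnitude impulse torque (N m)
#' @param impulse_onset_fraction fraction of the movement amplitude traversed
#'   at which the impulse fires
#' @param impulse_duration impulse duration (s), > 0 for `torque_impulse`
#' @return object of class `perturbation`
#' @export
perturbation <- function(kind = c("none", "inertia_delta", "damping_delta",
                                  "torque_impulse"),
                         inertia_delta = 0, damping_delta = 0,
                         constant_torque = 0, impulse_magnitude = 0,
                         impulse_onset_fraction = 0.25,
                         impulse_duration = 0.0375) {
  kind <- match.arg(kind)
  if (kind == "torque_impulse" && impulse_duration <= 0)
    stop("impulse_duration must be positive for kind = 'torque_impulse'")
  structure(list(kind = kind,
                 inertia_delta = if (kind == "inertia_delta") inertia_delta else 0,
                 damping_delta = if (kind == "damping_delta") damping_delta else 0,
                 constant_torque = constant_torque,
                 impulse_magnitude = if (kind == "torque_impulse") impulse_magnitude else 0,
                 impulse_onset_fraction = impulse_onset_fraction,
                 impulse_duration = impulse_duration),
            class = "perturbation")
}

#' Effective inertia and damping under a perturbation
#' @param geom an [arm_geometry()]
#' @param pert a [perturbation()]
#' @return list with `inertia` (kg m^2) and `damping` (N m s/rad)
#' @export
effective_plant <- function(geom, pert) {
  inertia <- geom$forearm_inertia_about_elbow + pert$inertia_delta
  if (inertia <= 0)
    stop("non-positive effective inertia (baseline + inertia_delta)")
  list(inertia = inertia,
       damping = geom$intrinsic_joint_damping + pert$damping_delta)
}

#' Elbow angular acceleration
#'
#' Single-DOF rigid-body dynamics:
#' `alpha = (tau_active - damping * omega + tau_bias + tau_impulse) / inertia`,
#' where the impulse torque is applied only while `pert_active`.
#'
#' @param state list or numeric with `elbow_angle` (rad) and `elbow_velocity`
#'   (rad/s)
#' @param active_joint_torque torque from the muscles (N m)
#' @param geom an [arm_geometry()]
#' @param pert a [perturbation()]
#' @param pert_active logical: is the torque impulse currently active?
#' @return elbow angular acceleration (rad/s^2)
#' @export
equations_of_motion <- function(state, active_joint_torque, geom,
                                pert = perturbation("none"),
                                pert_active = FALSE) {
  ep <- effective_plant(geom, pert)
  omega <- if (is.list(state)) state$elbow_velocity else state[2]
  imp <- if (isTRUE(pert_active)) pert$impulse_magnitude else 0
  (active_joint_torque - ep$damping * omega + pert$constant_torque + imp) /
    ep$inertia
}

#' Impulse onset angle
#'
#' The torque impulse fires the first time the traversed angle reaches
#' `impulse_onset_fraction` of the movement amplitude; the event is located by
#' the integrator's root finder during simulation.
#'
#' @param pert a [perturbation()] of kind `torque_impulse`
#' @param start_angle,end_angle movement endpoints (rad)
#' @return the elbow angle (rad) at which the impulse fires
#' @export
impulse_onset_angle <- function(pert, start_angle, end_angle) {
  stopifnot(pert$kind == "torque_impulse")
  start_angle + pert$impulse_onset_fraction * (end_angle - start_angle)
}
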