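# Hybrid controller: triphasic open-loop stimulation pattern (intermittent
# equilibrium-point control) plus time-delayed proportional-derivative
# feedback on muscle fiber length and contraction velocity, summed and
# clipped to [0, 1].

#' Triphasic open-loop stimulation pattern
#'
#' Piecewise-constant stimulation per muscle: a holding level `u0` before
#' movement onset, an acceleration phase (`u_acc` for agonists, `u_min` for
#' antagonists) until `t1`, a braking phase `u_dec` until `t2`, and a final
#' holding phase `u_final`. Branch boundaries are right-continuous (the value
#' of the later phase applies at the boundary instant).
#'
#' @param u0 per-muscle holding stimulations before movement onset
#' @param u_acc agonist stimulation during the acceleration phase (scalar)
#' @param u_min antagonist stimulation during the acceleration phase (scalar)
#' @param u_dec per-muscle braking-phase stimulations
#' @param u_final per-muscle final holding stimulations
#' @param t1 acceleration-to-braking switching time (s)
#' @param t2 braking-to-final switching time (s)
#' @param agonists integer indices of the agonist muscles for this movement
#' @param onset movement onset time (s)
#' @return object of class `triphasic_pattern`
#' @export
triphasic_pattern <- function(u0, u_acc, u_min, u_dec, u_final,
                              t1, t2, agonists, onset = 0.1) {
  n <- length(u0)
  stopifnot(length(u_dec) == n, length(u_final) == n,
            length(u_acc) == 1, length(u_min) == 1)
  if (!(onset < t1 && t1 < t2))
    stop("pattern requires onset < t1 < t2")
  all_u <- c(u0, u_acc, u_min, u_dec, u_final)
  if (any(all_u < 0 | all_u > 1))
    stop("all stimulations must lie in [0, 1]")
  if (length(agonists) == 0 || any(agonists < 1 | agonists > n))
    stop("agonists must be valid muscle indices")
  structure(list(u0 = u0, u_acc = u_acc, u_min = u_min, u_dec = u_dec,
                 u_final = u_final, t1 = t1, t2 = t2,
                 agonists = as.integer(agonists), onset = onset, n = n),
            class = "triphasic_pattern")
}

#' Evaluate the open-loop stimulation
#'
#' @param t time (s, scalar)
#' @param pattern a [triphasic_pattern()]
#' @return per-muscle stimulation vector
#' @export
open_loop_u <- function(t, pattern) {
  if (t < pattern$onset) return(pattern$u0)
  if (t < pattern$t1) {
    u <- rep(pattern$u_min, pattern$n)
    u[pattern$agonists] <- pattern$u_acc
    return(u)
  }
  if (t < pattern$t2) return(pattern$u_dec)
  pattern$u_final
}

#' Sum and clip open- and closed-loop stimulations
#'
#' Elementwise `u_open + u_closed`, clipped to `[0, 1]`.
#'
#' @param u_open,u_closed per-muscle stimulation vectors
#' @return total stimulation vector in `[0, 1]`
#' @export
total_u <- function(u_open, u_closed) {
  pmin(pmax(u_open + u_closed, 0), 1)
}

#' Feedback configuration
#'
#' Gains and neural delay of the delayed PD feedback on fiber length and
#' contraction velocity (Eq. `u_closed = kp/l_opt (l_ce - lambda) +
#' kd/l_opt (dl_ce - dlambda)`, evaluated at `t - delay`).
#'
#' @param k_p proportional gain (dimensionless; errors are normalized by
#'   `l_ce_opt`)
#' @param k_d derivative gain (s)
#' @param delay neural delay (s); 0.025 models a short-latency and 0.05 a
#'   long-latency stretch reflex
#' @param enabled logical; `FALSE` gives the pure open-loop controller
#' @return object of class `feedback_config`
#' @export
feedback_config <- function(k_p, k_d, delay = 0.05, enabled = TRUE) {
  if (delay < 0 || k_p < 0 || k_d < 0)
    stop("delay and gains must be non-negative")
  structure(list(k_p = k_p, k_d = k_d, delay = delay, enabled = enabled),
            class = "feedback_config")
}

#' Closed-loop stimulation component
#'
#' Pure evaluation of the delayed PD feedback law given the (already lagged)
#' fiber states and reference values. May be negative; clipping happens in
#' [total_u()].
#'
#' @param lce_lag,dlce_lag fiber lengths (m) and velocities (m/s) at `t - delay`
#' @param lambda_lag,dlambda_lag reference values at `t - delay`
#' @param cfg a [feedback_config()]
#' @param l_ce_opt per-muscle optimal CE lengths (m), used for normalization
#' @return per-muscle feedback stimulation (unclipped)
#' @export
closed_loop_u <- function(lce_lag, dlce_lag, lambda_lag, dlambda_lag,
                          cfg, l_ce_opt) {
  if (!isTRUE(cfg$enabled)) return(rep(0, length(lce_lag)))
  cfg$k_p / l_ce_opt * (lce_lag - lambda_lag) +
    cfg$k_d / l_ce_opt * (dlce_lag - dlambda_lag)
}

#' Record a reference trajectory from an unperturbed run
#'
#' Stores the fiber lengths and contraction velocities of an unperturbed
#' open-loop movement on its dense output grid, as the desired values
#' (lambda, dlambda) of the feedback law. Replaying the closed-loop
#' controller on the identical unperturbed setup then yields a vanishing
#' closed-loop signal.
#'
#' @param res a `sim_result` from an unperturbed run without feedback
#' @param delay the feedback delay the reference will serve (s); used to check
#'   that the recording grid is fine enough
#' @return object of class `reference_trajectory`
#' @export
record_reference <- function(res, delay = 0.05) {
  stopifnot(inherits(res, "sim_result"))
  if (!is.null(res$pert) && res$pert$kind != "none")
    stop("reference must be recorded from an unperturbed run")
  if (!is.null(res$feedback) && isTRUE(res$feedback$enabled))
    stop("reference must be recorded from a run without feedback")
  # use the raw solver time base when present (it contains the exact segment
  # boundaries, so a closed-loop replay builds its delay history on the very
  # same nodes and the feedback error stays at numerical zero)
  if (!is.null(res$raw_time)) {
    tt <- res$raw_time; lce <- res$raw_lce; dlce <- res$raw_dlce
  } else {
    tt <- res$time; lce <- res$lce; dlce <- res$dlce
  }
  if (delay > 0 && max(diff(tt)) > delay)
    stop("recording grid is coarser than the feedback delay")
  n <- ncol(lce)
  lam <- lapply(seq_len(n), function(i)
    stats::splinefun(tt, lce[, i], method = "fmm"))
  dlam <- lapply(seq_len(n), function(i)
    stats::splinefun(tt, dlce[, i], method = "fmm"))
  structure(list(t_min = tt[1], t_max = tt[length(tt)], n = n,
                 lambda = lam, dlambda = dlam,
                 sp = multi_hermite(tt, lce, dlce),
                 spd = multi_linear(tt, dlce),
                 lce0 = lce[1, ], time = tt,
                 lce = lce, dlce = dlce),
            class = "reference_trajectory")
}

#' Evaluate a reference trajectory
#'
#' @param ref a [record_reference()] result
#' @param t time (s, scalar); times before the recording start return the
#'   initial (equilibrium) values
#' @return list with `lambda` and `dlambda` per-muscle vectors
#' @export
eval_reference <- function(ref, t) {
  if (t > ref$t_max + 1e-9)
    stop("reference trajectory truncated before requested time")
  if (t <= ref$t_min)
    return(list(lambda = ref$lce0, dlambda = rep(0, ref$n)))
  list(lambda = vapply(ref$lambda, function(f) f(t), numeric(1)),
       dlambda = vapply(ref$dlambda, function(f) f(t), numeric(1)))
}

#' Solve equilibrium stimulations at a posture
#'
#' Finds per-muscle stimulations that put the arm in a stable equilibrium at
#' a target angle: the net joint torque (muscle torque plus any constant bias
#' torque) vanishes at the steady state of the activation dynamics and the
#' isometric muscle equilibrium. Among the feasible sets, the stimulations
#' stay as close as possible to a desired co-contraction level `u_des`: the
#' solver applies the minimum-norm correction along the torque-sensitivity
#' direction and locates the exact torque zero along it. `objective =
#' "total"` instead minimizes total stimulation (sets `u_des = 0`), the
#' literal reading of the co-contraction objective.
#'
#' @param model an [build_model()] model
#' @param target_angle target elbow angle (rad)
#' @param u_des desired co-contraction level in `[0, 1]`
#' @param external_torque constant bias torque to balance (N m)
#' @param torque_tolerance admissible net-torque residual (N m)
#' @param objective `"deviation"` (default) or `"total"`
#' @return list with `u` (per-muscle stimulations), `torque_residual`,
#'   `l_ce`, `activity`, `force`
#' @export
solve_equilibrium_stimulations <- function(model, target_angle, u_des = 0.1,
                                           external_torque = 0,
                                           torque_tolerance = 1e-6,
                                           objective = c("deviation", "total")) {
  objective <- match.arg(objective)
  if (objective == "total") u_des <- 0
  rng <- model$geom$elbow_range
  if (target_angle < rng[1] || target_angle > rng[2])
    stop("target angle outside the anatomical range")
  n <- model$n_muscles
  lens <- vapply(seq_len(n), function(i)
    mtu_path_length(target_angle, model$muscles[[i]]$path), numeric(1))
  arms <- vapply(seq_len(n), function(i)
    moment_arm(target_angle, model$muscles[[i]]$path), numeric(1))
  net_torque <- function(u) {
    f <- vapply(seq_len(n), function(i)
      isometric_equilibrium(lens[i], u[i], model$muscles[[i]]$params)$force,
      numeric(1))
    sum(arms * f) + external_torque
  }
  base <- pmin(pmax(rep(u_des, n), 0), 1)
  # torque sensitivity direction at the co-contraction baseline
  du <- 1e-3
  sens <- vapply(seq_len(n), function(i) {
    up <- base; up[i] <- min(up[i] + du, 1)
    um <- base; um[i] <- max(um[i] - du, 0)
    (net_torque(up) - net_torque(um)) / sum(up[i] - um[i])
  }, numeric(1))
  if (all(abs(sens) < 1e-12)) stop("degenerate torque sensitivity")
  dir <- sens / sqrt(sum(sens^2))
  u_of <- function(beta) pmin(pmax(base + beta * dir, 0), 1)
  g <- function(beta) net_torque(u_of(beta))
  lo <- -2; hi <- 2
  glo <- g(lo); ghi <- g(hi)
  if (glo * ghi > 0) {
    dirn <- if (abs(glo) < abs(ghi)) "extension" else "flexion"
    stop(sprintf(
      "no stimulation set balances the torque (infeasible toward %s)", dirn))
  }
  beta <- stats::uniroot(g, lower = lo, upper = hi, tol = 1e-12)$root
  u <- u_of(beta)
  eq <- lapply(seq_len(n), function(i)
    isometric_equilibrium(lens[i], u[i], model$muscles[[i]]$params))
  resid <- sum(arms * vapply(eq, `[[`, numeric(1), "force")) + external_torque
  if (abs(resid) > torque_tolerance)
    stop(sprintf("equilibrium residual %.3g exceeds tolerance %.3g",
                 resid, torque_tolerance))
  list(u = u, torque_residual = resid,
       l_ce = vapply(eq, `[[`, numeric(1), "l_ce"),
       activity = vapply(eq, `[[`, numeric(1), "activity"),
       force = vapply(eq, `[[`, numeric(1), "force"))
}
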