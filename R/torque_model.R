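# Idealized torque-driven comparison model: the same rigid plant driven by
# the net joint torque recorded from the musculoskeletal model's unperturbed
# movement, optionally with delayed (100 ms) PD feedback on the joint-angle
# error relative to the desired minimum-jerk trajectory.

# cubic Hermite interpolant with centered-difference slopes (one-sided ends)
multi_hermite_cr <- function(x, Y) {
  Y <- as.matrix(Y)
  n <- length(x)
  dY <- Y
  dY[2:(n - 1), ] <- (Y[3:n, , drop = FALSE] - Y[1:(n - 2), , drop = FALSE]) /
    (x[3:n] - x[1:(n - 2)])
  dY[1, ] <- (Y[2, ] - Y[1, ]) / (x[2] - x[1])
  dY[n, ] <- (Y[n, ] - Y[n - 1, ]) / (x[n] - x[n - 1])
  multi_hermite(x, Y, dY)
}

#' Record the net joint torque of a run
#'
#' Interpolant of the active joint torque time series, used to drive the
#' torque-based comparison model.
#'
#' @param res a `sim_result` with diagnostics
#' @return function of time returning the recorded torque (N m)
#' @export
record_net_torque <- function(res) {
  if (is.null(res$torque_active)) stop("run has no torque diagnostics")
  sp <- multi_hermite_cr(res$time, matrix(res$torque_active, ncol = 1))
  tmax <- max(res$time)
  function(t) multi_spline_eval(sp, min(max(t, 0), tmax))[1]
}

#' Simulate the torque-driven comparison model
#'
#' The plant (same inertia/damping, including any perturbation deltas) is
#' driven by a recorded torque profile; with feedback enabled, a delayed PD
#' controller on the joint-angle error relative to the desired minimum-jerk
#' trajectory is added (delay 100 ms, a long-latency joint-level reflex).
#'
#' @param model an `nms_model` (plant parameters and torque-model config)
#' @param torque_fun recorded torque as a function of time, see
#'   [record_net_torque()]
#' @param plan the [movement_plan()] of the recorded movement
#' @param pert a [perturbation()]
#' @param feedback_on enable the delayed joint-angle PD feedback
#' @param horizon,dt_out,rtol simulation settings
#' @return object of class `sim_result` (kinematics and impulse bookkeeping;
#'   no muscle-level fields)
#' @export
simulate_torque_model <- function(model, torque_fun, plan,
                                  pert = perturbation("none"),
                                  feedback_on = FALSE, horizon = 1,
                                  dt_out = 1e-3, rtol = 1e-5) {
  tm <- model$config$experiments$torque_model
  ep <- effective_plant(model$geom, pert)
  rng <- model$geom$elbow_range
  delay <- tm$delay
  phi0 <- plan$start_angle

  hist_sp <- NULL
  hist_t_max <- 0
  impulse_active <- FALSE

  rhs <- function(t, y, parms) {
    phi <- y[1]; omega <- y[2]
    if (phi < rng[1] || phi > rng[2])
      stop(sprintf("elbow angle %.1f deg outside anatomical range",
                   phi * 180 / pi))
    tau_fb <- 0
    if (feedback_on) {
      tl <- t - delay
      if (tl <= 0) {
        phi_l <- phi0; om_l <- 0
      } else {
        st <- multi_spline_eval(hist_sp, tl)
        phi_l <- st[1]; om_l <- st[2]
      }
      des <- desired_trajectory(tl, plan)
      tau_fb <- tm$k_p * (des$angle - phi_l) + tm$k_d * (des$velocity - om_l)
    }
    imp <- if (impulse_active) pert$impulse_magnitude else 0
    alpha <- (torque_fun(t) + tau_fb - ep$damping * omega +
                pert$constant_torque + imp) / ep$inertia
    list(c(omega, alpha), alpha = alpha)
  }

  imp_pending <- pert$kind == "torque_impulse" && pert$impulse_magnitude != 0
  imp_t_on <- NA_real_; imp_t_off <- NA_real_
  onset_angle <- if (imp_pending)
    impulse_onset_angle(pert, plan$start_angle, plan$end_angle) else NA_real_
  if (imp_pending && pert$impulse_onset_fraction == 0) {
    imp_t_on <- plan$onset; imp_t_off <- imp_t_on + pert$impulse_duration
    imp_pending <- FALSE
  }

  bp <- c(0, plan$onset, horizon)
  if (feedback_on) bp <- c(bp, seq(delay, horizon, by = delay))
  if (!is.na(imp_t_on)) bp <- c(bp, imp_t_on, imp_t_off)
  bp <- sort(unique(pmin(pmax(bp, 0), horizon)))
  grid <- seq(0, horizon, by = dt_out)
  y <- c(phi0, 0)
  out_t <- 0; out_y <- matrix(y, nrow = 1); out_a <- rhs(0, y, NULL)$alpha

  k <- 1
  while (k < length(bp)) {
    t_a <- bp[k]; t_b <- bp[k + 1]
    if (t_b - t_a < 1e-12) { k <- k + 1; next }
    impulse_active <- !is.na(imp_t_on) &&
      t_a >= imp_t_on - 1e-12 && t_b <= imp_t_off + 1e-12
    g <- grid[grid > t_a + 1e-12 & grid < t_b - 1e-12]
    times <- unique(c(t_a, g, t_b))
    rootf <- if (imp_pending) function(t, y, parms) y[1] - onset_angle else NULL
    sol <- suppressWarnings(
      deSolve::lsoda(y, times, rhs, parms = NULL, rtol = rtol,
                     atol = 1e-8, rootfunc = rootf, tcrit = t_b,
                     maxsteps = 2000))
    if (nrow(sol) < length(times) && !(imp_pending && length(attributes(sol)$troot)))
      stop(sprintf("integration stalled in segment [%.3f, %.3f]", t_a, t_b))
    troot <- attributes(sol)$troot
    tt <- sol[, 1]; yy <- sol[, -1, drop = FALSE]
    keep <- tt > out_t[length(out_t)] + 1e-12
    if (any(keep)) {
      out_t <- c(out_t, tt[keep])
      out_y <- rbind(out_y, yy[keep, 1:2, drop = FALSE])
      out_a <- c(out_a, yy[keep, 3])
      if (feedback_on)
        hist_sp <- multi_hermite(out_t, out_y,
                                 cbind(out_y[, 2], out_a))
    }
    y <- yy[nrow(yy), 1:2]
    if (imp_pending && length(troot) && !is.na(troot[1]) &&
        troot[1] < t_b - 1e-12) {
      imp_t_on <- troot[1]
      imp_t_off <- imp_t_on + pert$impulse_duration
      imp_pending <- FALSE
      rest <- c(bp[bp > imp_t_on + 1e-12], imp_t_off, horizon)
      rest <- sort(unique(rest[rest <= horizon + 1e-12]))
      bp <- c(imp_t_on, rest)
      k <- 1
      next
    }
    k <- k + 1
  }
  if (imp_pending)
    warning("torque impulse never fired: movement did not reach the onset fraction")

  keep <- vapply(grid, function(g) which.min(abs(out_t - g)), integer(1))
  structure(list(
    time = out_t[keep], phi = out_y[keep, 1], omega = out_y[keep, 2],
    alpha = out_a[keep],
    pert = pert, plan = plan,
    feedback = list(enabled = feedback_on, delay = delay,
                    k_p = tm$k_p, k_d = tm$k_d),
    impulse = list(fired = !is.na(imp_t_on), t_on = imp_t_on,
                   t_off = imp_t_off),
    muscle_names = character(0), dt_out = dt_out,
    inertia = ep$inertia, damping = ep$damping,
    model_kind = "torque"), class = "sim_result")
}
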