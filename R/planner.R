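#' Minimum-jerk movement plan
#'
#' Defines a point-to-point elbow movement as a fifth-order (minimum-jerk)
#' polynomial between a start and an end angle, with zero velocity and
#' acceleration at both ends. Outside the movement window the plan clamps to
#' the endpoint values.
#'
#' @param start_angle start elbow angle (rad, flexion positive)
#' @param end_angle end elbow angle (rad)
#' @param onset movement onset time (s)
#' @param duration movement duration (s), must be positive
#' @return an object of class `movement_plan`
#' @export
movement_plan <- function(start_angle, end_angle, onset = 0.1, duration = 0.6) {
  stopifnot(is.finite(start_angle), is.finite(end_angle))
  if (duration <= 0) stop("movement duration must be positive")
  if (onset < 0) stop("movement onset must be non-negative")
  structure(
    list(start_angle = start_angle, end_angle = end_angle,
         onset = onset, duration = duration),
    class = "movement_plan"
  )
}

#' Evaluate the desired minimum-jerk trajectory
#'
#' @param t time(s) at which to evaluate (s); vectorized
#' @param plan a [movement_plan()]
#' @return list with components `angle` (rad), `velocity` (rad/s) and
#'   `acceleration` (rad/s^2), each the length of `t`
#' @export
desired_trajectory <- function(t, plan) {
  stopifnot(inherits(plan, "movement_plan"))
  s <- (t - plan$onset) / plan$duration
  s <- pmin(pmax(s, 0), 1)
  amp <- plan$end_angle - plan$start_angle
  p <- 10 * s^3 - 15 * s^4 + 6 * s^5
  v <- (30 * s^2 - 60 * s^3 + 30 * s^4) / plan$duration
  a <- (60 * s - 180 * s^2 + 120 * s^3) / plan$duration^2
  list(angle = plan$start_angle + amp * p,
       velocity = amp * v,
       acceleration = amp * a)
}

#' @export
print.movement_plan <- function(x, ...) {
  cat(sprintf(
    "<movement_plan> %.1f deg -> %.1f deg, onset %.3f s, duration %.3f s\n",
    x$start_angle * 180 / pi, x$end_angle * 180 / pi, x$onset, x$duration))
  invisible(x)
}
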