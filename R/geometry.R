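# Planar muscle-path geometry with via-ellipse deflection.
#
# Frames: the shoulder is locked, so the upper arm is the ground segment.
# World frame: elbow joint at the origin; the upper-arm axis (elbow->shoulder)
# points along world angle pi; the forearm axis (elbow->wrist) points along
# world angle phi, where phi is the elbow flexion angle (phi = 0 full
# extension, flexion positive = counter-clockwise).
# Segment frames: x-axis along the segment away from the elbow.

#' Deflection ellipse attached to a segment
#'
#' @param segment `"upper_arm"` or `"forearm"` (the bone the ellipse is fixed to)
#' @param center ellipse center in the owning segment's frame (m, length 2)
#' @param semi_axes semi-axis lengths (m, length 2), axis-aligned in the
#'   owning frame; strictly positive
#' @return object of class `ellipse_spec`
#' @export
ellipse_spec <- function(segment, center, semi_axes) {
  segment <- match.arg(segment, c("upper_arm", "forearm"))
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  stopifnot(length(center) == 2, length(semi_axes) == 2)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("ellipse semi-axes must be strictly positive")
  structure(list(segment = segment, center = center, semi_axes = semi_axes),
            class = "ellipse_spec")
}

#' Muscle path specification
#'
#' A muscle path runs from an origin point fixed to one segment to an
#' insertion point fixed to the other, optionally deflected around ellipses
#' fixed to the bones (shortest route not penetrating any ellipse).
#'
#' @param origin origin point in the upper-arm frame (m, length 2)
#' @param insertion insertion point in the forearm frame (m, length 2)
#' @param ellipses list of [ellipse_spec()] obstacles (may be empty)
#' @param name optional muscle name used in messages and output headers
#' @return object of class `path_spec`
#' @export
path_spec <- function(origin, insertion, ellipses = list(), name = "muscle") {
  origin <- as.numeric(origin); insertion <- as.numeric(insertion)
  stopifnot(length(origin) == 2, length(insertion) == 2)
  if (length(ellipses) && !all(vapply(ellipses, inherits, TRUE, "ellipse_spec")))
    stop("ellipses must be a list of ellipse_spec objects")
  sp <- structure(list(origin = origin, insertion = insertion,
                       ellipses = ellipses, name = name),
                  class = "path_spec")
  # endpoints must sit outside their own segment's ellipses
  for (el in ellipses) {
    pt <- if (el$segment == "upper_arm") origin else insertion
    loc <- (pt - el$center) / el$semi_axes
    if (sum(loc^2) <= 1)
      stop(sprintf("path '%s': endpoint lies inside a deflection ellipse", name))
  }
  sp
}

rot2 <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, -s_, c_), 2, 2)
}

# segment-frame point -> world, given elbow angle phi
seg_to_world <- function(p, segment, phi) {
  if (segment == "upper_arm") c(-p[1], -p[2]) else drop(rot2(phi) %*% p)
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}
.gl24 <- gauss_legendre(24)

# arc length of ellipse (a, b) from angle th0 to th1 (signed direction handled
# by caller passing th1 > th0)
ellipse_arc_length <- function(a, b, th0, th1) {
  mid <- (th0 + th1) / 2; half <- (th1 - th0) / 2
  th <- mid + half * .gl24$x
  sum(.gl24$w * sqrt((a * sin(th))^2 + (b * cos(th))^2)) * half
}

# tangent angles on axis-aligned ellipse (a, b) centered at origin, from
# external point p (local frame): b*px*cos(th) + a*py*sin(th) = a*b
ellipse_tangent_angles <- function(a, b, p) {
  r <- sqrt((b * p[1])^2 + (a * p[2])^2)
  if (r < a * b) return(NULL)                 # point inside: no tangent
  psi <- atan2(a * p[2], b * p[1])
  dth <- acos(pmin(1, a * b / r))
  c(psi + dth, psi - dth)
}

# does segment p-q (local ellipse frame) intersect the open interior?
segment_hits_ellipse <- function(a, b, p, q) {
  p <- p / c(a, b); q <- q / c(a, b)          # map ellipse to unit circle
  d <- q - p
  t <- -sum(p * d) / sum(d * d)
  t <- min(max(t, 0), 1)
  sum((p + t * d)^2) < 1 - 1e-12
}

# shortest wrap of a path p -> q around one ellipse (local frame), for both
# travel directions; returns NULL when no valid wrap exists
wrap_one_ellipse <- function(a, b, p, q) {
  th_p <- ellipse_tangent_angles(a, b, p)
  th_q <- ellipse_tangent_angles(a, b, q)
  if (is.null(th_p) || is.null(th_q))
    stop("path endpoint inside a deflection ellipse")
  epoint <- function(th) c(a * cos(th), b * sin(th))
  etan <- function(th) c(-a * sin(th), b * cos(th))
  best <- NULL
  for (dir in c(1, -1)) {
    # tangent point leaving p whose travel direction continues the arc in dir
    tp <- NULL
    for (th in th_p) {
      tpt <- epoint(th)
      if (sum((tpt - p) * (dir * etan(th))) > 0) tp <- list(th = th, pt = tpt)
    }
    tq <- NULL
    for (th in th_q) {
      tpt <- epoint(th)
      if (sum((q - tpt) * (dir * etan(th))) > 0) tq <- list(th = th, pt = tpt)
    }
    if (is.null(tp) || is.null(tq)) next
    dth <- (dir * (tq$th - tp$th)) %% (2 * pi)
    arc <- ellipse_arc_length(a, b, 0, dth)
    len <- sqrt(sum((tp$pt - p)^2)) + arc + sqrt(sum((q - tq$pt)^2))
    if (is.null(best) || len < best$length)
      best <- list(length = len, t1 = tp$pt, t2 = tq$pt, arc = arc, dir = dir)
  }
  best
}

#' Solve a muscle path at a given elbow angle
#'
#' Computes the shortest origin-to-insertion route that does not penetrate any
#' deflection ellipse (straight segments plus elliptical arcs), its length,
#' and the geometry needed for contact-force evaluation.
#'
#' @param phi elbow flexion angle (rad)
#' @param spec a [path_spec()]
#' @return list with `length` (m), `deflected` (logical), `points` (matrix of
#'   the polyline anchor points in world coordinates: origin, tangent points
#'   if any, insertion) and per-ellipse wrap details in `wraps`
#' @export
solve_path <- function(phi, spec) {
  O <- seg_to_world(spec$origin, "upper_arm", phi)
  I <- seg_to_world(spec$insertion, "forearm", phi)
  # world-frame ellipse data (axis-aligned in owner frame; rotate points into
  # the owner frame instead of rotating the ellipse)
  to_local <- function(el, p) {
    if (el$segment == "upper_arm") q <- c(-p[1], -p[2])
    else q <- drop(rot2(-phi) %*% p)
    q - el$center
  }
  to_world <- function(el, p) {
    p <- p + el$center
    if (el$segment == "upper_arm") c(-p[1], -p[2]) else drop(rot2(phi) %*% p)
  }
  pts <- list(O)
  wraps <- vector("list", length(spec$ellipses))
  total <- 0
  cur <- O
  deflected <- FALSE
  # sequential wrap: ellipses are ordered along the path (config convention);
  # each wrapped ellipse advances the running start point to its exit tangent
  for (k in seq_along(spec$ellipses)) {
    el <- spec$ellipses[[k]]
    a <- el$semi_axes[1]; b <- el$semi_axes[2]
    pl <- to_local(el, cur); ql <- to_local(el, I)
    if (!segment_hits_ellipse(a, b, pl, ql)) next
    w <- wrap_one_ellipse(a, b, pl, ql)
    if (is.null(w)) next
    t1w <- to_world(el, w$t1); t2w <- to_world(el, w$t2)
    total <- total + sqrt(sum((t1w - cur)^2)) + w$arc
    wraps[[k]] <- list(t1 = t1w, t2 = t2w, arc = w$arc,
                       from = cur)
    pts <- c(pts, list(t1w, t2w))
    cur <- t2w
    deflected <- TRUE
  }
  total <- total + sqrt(sum((I - cur)^2))
  pts <- c(pts, list(I))
  list(length = total, deflected = deflected,
       points = do.call(rbind, pts), wraps = wraps,
       origin_world = O, insertion_world = I)
}

#' Muscle-tendon path length
#'
#' @param phi elbow flexion angle(s) (rad); vectorized
#' @param spec a [path_spec()]
#' @return path length(s) in m
#' @export
mtu_path_length <- function(phi, spec) {
  vapply(phi, function(p) solve_path(p, spec)$length, numeric(1))
}

#' Moment arm about the elbow (tendon excursion)
#'
#' The moment arm is defined as minus the derivative of the muscle path length
#' with respect to the elbow angle, so a flexor (which shortens during
#' flexion) has a positive moment arm. Evaluated by Richardson-extrapolated
#' central differences of [solve_path()].
#'
#' @param phi elbow flexion angle(s) (rad); vectorized
#' @param spec a [path_spec()]
#' @param h base finite-difference step (rad)
#' @return moment arm(s) in m
#' @export
moment_arm <- function(phi, spec, h = 1e-4) {
  one <- function(p) {
    d1 <- -(mtu_path_length(p + h, spec) - mtu_path_length(p - h, spec)) / (2 * h)
    d2 <- -(mtu_path_length(p + h / 2, spec) -
              mtu_path_length(p - h / 2, spec)) / h
    (4 * d2 - d1) / 3
  }
  vapply(phi, one, numeric(1))
}

#' Precompute fast length/moment-arm interpolants for a path
#'
#' Builds cubic-spline interpolants of path length and moment arm over the
#' anatomical range, used inside the simulation right-hand side where exact
#' geometry solving would dominate the runtime.
#'
#' @param spec a [path_spec()]
#' @param range anatomical elbow range (rad, length 2)
#' @param n grid resolution
#' @return list with functions `length(phi)` and `moment_arm(phi)`
#' @export
routing_functions <- function(spec, range, n = 241) {
  grid <- seq(range[1], range[2], length.out = n)
  L <- mtu_path_length(grid, spec)
  r <- moment_arm(grid, spec)
  lf <- stats::splinefun(grid, L, method = "fmm")
  rf <- stats::splinefun(grid, r, method = "fmm")
  list(length = lf, moment_arm = rf)
}

#' Internal loads: active joint torque, contact and constraint forces
#'
#' Given the muscle tendon forces at one instant, computes the active elbow
#' torque (sum of moment arm times force), the muscle-bone contact force at
#' each deflection ellipse (vector sum of the two path-tension directions at
#' the wrap), and the elbow joint constraint force closing the Newton-Euler
#' force balance of the forearm.
#'
#' @param phi elbow angle (rad)
#' @param omega elbow angular velocity (rad/s)
#' @param alpha elbow angular acceleration (rad/s^2)
#' @param forces per-muscle tendon forces (N, non-negative)
#' @param specs list of [path_spec()], same order as `forces`
#' @param geom an [arm_geometry()] (forearm mass and center-of-mass distance)
#' @return list with `active_torque` (N·m), `constraint_force` (world-frame
#'   2-vector, N), `contact` (per muscle: matrix with one row per ellipse,
#'   columns fx, fy, magnitude; zero rows where the path is straight) and
#'   `first_contact_magnitude` (per muscle, N; the first deflection ellipse)
#' @export
joint_loads <- function(phi, omega, alpha, forces, specs, geom) {
  stopifnot(length(forces) == length(specs))
  if (any(forces < -1e-9)) stop("muscle forces must be non-negative")
  n <- length(specs)
  tau <- 0
  f_forearm <- c(0, 0)  # muscle + contact forces acting on the forearm
  contact <- vector("list", n)
  first_mag <- numeric(n)
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    sol <- solve_path(phi, sp)
    r <- moment_arm(phi, sp)
    tau <- tau + r * forces[i]
    ne <- length(sp$ellipses)
    cm <- matrix(0, nrow = max(ne, 1), ncol = 3,
                 dimnames = list(NULL, c("fx", "fy", "magnitude")))
    seen_first <- FALSE
    for (k in seq_len(ne)) {
      w <- sol$wraps[[k]]
      if (is.null(w)) next
      u1 <- (w$from - w$t1); u1 <- u1 / sqrt(sum(u1^2))
      # exit side: next anchor after t2 along the path
      nxt <- sol$insertion_world
      for (k2 in seq_along(sol$wraps)[-seq_len(k)]) {
        if (!is.null(sol$wraps[[k2]])) { nxt <- sol$wraps[[k2]]$from; break }
      }
      u2 <- (nxt - w$t2); u2 <- u2 / sqrt(sum(u2^2))
      fc <- forces[i] * (u1 + u2)   # path pulls the bone toward both anchors
      cm[k, ] <- c(fc, sqrt(sum(fc^2)))
      if (!seen_first) { first_mag[i] <- cm[k, 3]; seen_first <- TRUE }
      if (sp$ellipses[[k]]$segment == "forearm") f_forearm <- f_forearm + fc
    }
    contact[[i]] <- cm
    # insertion tension pulls the forearm toward the previous path anchor
    np <- nrow(sol$points)
    prev <- sol$points[np - 1, ]
    ui <- prev - sol$insertion_world
    nrm <- sqrt(sum(ui^2))
    if (nrm > 0 && forces[i] > 0)
      f_forearm <- f_forearm + forces[i] * ui / nrm
  }
  # forearm center-of-mass acceleration (rotation about the fixed elbow)
  d <- geom$forearm_com_distance
  rhat <- c(cos(phi), sin(phi)); that <- c(-sin(phi), cos(phi))
  a_com <- d * (alpha * that - omega^2 * rhat)
  constraint <- geom$forearm_mass * a_com - f_forearm
  names(first_mag) <- vapply(specs, function(s) s$name, character(1))
  list(active_torque = tau, constraint_force = constraint,
       contact = contact, first_contact_magnitude = first_mag)
}
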