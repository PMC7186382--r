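# The circular special case has a closed form: for an obstructing circle of
# radius r centered at c, the wrap length is the two tangent segments plus
# the connecting arc. Used as the analytic oracle for the path solver.
circle_wrap_length <- function(A, B, C, r) {
  dA <- sqrt(sum((A - C)^2)); dB <- sqrt(sum((B - C)^2))
  tA <- sqrt(dA^2 - r^2); tB <- sqrt(dB^2 - r^2)
  ang <- function(P, d, t) atan2(t, r)  # angle between CP and the tangent point
  # angle at the center between the two tangent-point radii
  gamma <- acos(sum((A - C) * (B - C)) / (dA * dB)) -
    acos(r / dA) - acos(r / dB)
  tA + tB + r * gamma
}

test_that("an ellipse far from the chord leaves the path straight", {
  sp <- path_spec(origin = c(0.2, 0), insertion = c(0.2, 0),
                  ellipses = list(ellipse_spec("upper_arm", c(0.1, 0.3),
                                               c(0.02, 0.02))))
  sol <- solve_path(pi / 2, sp)
  o <- sol$origin_world; i <- sol$insertion_world
  expect_false(sol$deflected)
  expect_equal(sol$length, sqrt(sum((o - i)^2)), tolerance = 1e-12)
})

test_that("the circular wrap length matches the closed form to 1e-9 m", {
  # olecranon-style circular obstacle on the forearm, wrapped at deep flexion
  r <- 0.02
  ctr <- c(0, -0.006)
  sp <- path_spec(origin = c(0.22, 0.012), insertion = c(-0.025, -0.011),
                  ellipses = list(ellipse_spec("forearm", ctr, c(r, r))))
  rot <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  for (phi in c(2.3, 2.5, 2.7)) {
    sol <- solve_path(phi, sp)
    expect_true(sol$deflected)
    C <- drop(rot(phi) %*% ctr)
    expect_equal(sol$length,
                 circle_wrap_length(sol$origin_world, sol$insertion_world,
                                    C, r),
                 tolerance = 1e-9)
  }
})

test_that("shrinking the obstructing ellipse strictly shortens the path", {
  mk <- function(ax) path_spec(origin = c(0.22, 0.012), insertion = c(-0.025, -0.011),
                               ellipses = list(ellipse_spec("forearm", c(0, -0.006), ax)))
  big <- solve_path(2.5, mk(c(0.024, 0.02)))
  small <- solve_path(2.5, mk(c(0.012, 0.01)))
  expect_true(big$deflected)
  expect_lt(small$length, big$length)
  # and the path can never be shorter than the straight chord
  chord <- sqrt(sum((big$origin_world - big$insertion_world)^2))
  expect_gte(small$length, chord)
})

test_that("moment arm equals the central finite difference of the path length", {
  model <- test_model()
  h <- 1e-5
  for (nm in model$muscle_names) {
    sp <- model$muscles[[nm]]$path
    for (phi in c(0.6, 1.0, 1.5)) {
      fd <- -(mtu_path_length(phi + h, sp) - mtu_path_length(phi - h, sp)) / (2 * h)
      expect_equal(moment_arm(phi, sp), fd, tolerance = 1e-6)
    }
  }
})

test_that("an undeflected straight path has |moment arm| equal to its distance from the joint", {
  # path crossing the joint region at perpendicular distance d, no ellipse
  d <- 0.025
  sp <- path_spec(origin = c(0.2, -d), insertion = c(0.08, d / 2))
  phi <- 0.9
  sol <- solve_path(phi, sp)
  o <- sol$origin_world; i <- sol$insertion_world
  u <- (i - o) / sqrt(sum((i - o)^2))
  dist <- abs(u[1] * (-o[2]) - u[2] * (-o[1]))
  expect_equal(abs(moment_arm(phi, sp)), dist, tolerance = 1e-5)
})

test_that("mirrored flexor/extensor geometry gives opposite moment arms", {
  # mirroring the whole geometry about the extended-arm axis maps the path at
  # elbow angle phi onto the original at -phi, so r_mirror(phi) = -r(-phi)
  mk <- function(s) path_spec(origin = c(0.2, -s * 0.015),
                              insertion = c(0.05, s * 0.01),
                              ellipses = list(ellipse_spec("upper_arm",
                                                           c(0, -s * 0.004),
                                                           c(0.024, 0.02))))
  for (phi in c(0.3, 0.7)) {
    expect_equal(moment_arm(phi, mk(-1)), -moment_arm(-phi, mk(1)),
                 tolerance = 1e-8)
    expect_equal(mtu_path_length(phi, mk(-1)), mtu_path_length(-phi, mk(1)),
                 tolerance = 1e-12)
  }
})

test_that("joint loads: zero forces give zero constraint force, and loads scale linearly", {
  model <- test_model()
  specs <- lapply(model$muscles, `[[`, "path")
  z <- joint_loads(1.0, 0, 0, rep(0, 4), specs, model$geom)
  expect_equal(sqrt(sum(z$constraint_force^2)), 0, tolerance = 1e-12)
  expect_equal(z$active_torque, 0)
  f <- c(120, 80, 60, 90)
  a <- joint_loads(1.0, 0, 0, f, specs, model$geom)
  b <- joint_loads(1.0, 0, 0, 2 * f, specs, model$geom)
  expect_equal(b$active_torque, 2 * a$active_torque, tolerance = 1e-12)
  expect_equal(b$first_contact_magnitude, 2 * a$first_contact_magnitude,
               tolerance = 1e-12)
})

test_that("contact force vanishes on straight paths and pushes toward the wrapped side", {
  sp_straight <- path_spec(origin = c(0.2, -0.05), insertion = c(0.1, 0.05))
  geom <- test_model()$geom
  jl <- joint_loads(1.2, 0, 0, 100, list(sp_straight), geom)
  expect_equal(jl$first_contact_magnitude[[1]], 0)
  # wrapped circle on the forearm: resultant points from the contact region
  # across the center (the path presses the bone)
  r <- 0.02
  sp <- path_spec(origin = c(0.22, 0.012), insertion = c(-0.025, -0.011),
                  ellipses = list(ellipse_spec("forearm", c(0, -0.006), c(r, r))))
  phi <- 2.5
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  C <- drop(rot %*% c(0, -0.006))
  sol <- solve_path(phi, sp)
  jl2 <- joint_loads(phi, 0, 0, 100, list(sp), geom)
  fc <- jl2$contact[[1]][1, c("fx", "fy")]
  mid <- (sol$wraps[[1]]$t1 + sol$wraps[[1]]$t2) / 2   # contact region
  expect_gt(sum(fc * (C - mid)), 0)
  expect_gt(jl2$first_contact_magnitude[[1]], 0)
})

test_that("joint power balances the summed muscle shortening power on a trajectory", {
  model <- test_model()
  calib <- test_calibration()
  res <- calib$recording
  # power from torque vs from fiber-path shortening, using finite differences
  # of the reported path lengths (independent of the moment-arm route)
  dt <- diff(res$time[1:2])
  dL <- apply(res$lmtu, 2, function(l) c(NA, diff(l) / dt))
  p_mus <- rowSums(-dL * res$force)
  p_joint <- res$torque_active * res$omega
  i <- 100:900
  scale <- max(abs(p_joint[i]))
  expect_lt(max(abs(p_joint[i] - p_mus[i]), na.rm = TRUE), 0.02 * scale)
})

test_that("geometry errors are raised for endpoints inside an ellipse", {
  expect_error(
    path_spec(origin = c(0.005, 0), insertion = c(0.1, 0.01),
              ellipses = list(ellipse_spec("upper_arm", c(0, 0), c(0.02, 0.02)))),
    "inside")
  expect_error(ellipse_spec("upper_arm", c(0, 0), c(-0.01, 0.02)), "positive")
})
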