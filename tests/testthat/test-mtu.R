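p0 <- mtu_params(f_max = 400, l_ce_opt = 0.11, see_rest_length = 0.105)

test_that("activation converges to the lower fixed point without stimulation", {
  rhs <- function(t, y, p) list(activation_rate(y, 0, p0$l_ce_opt, p0))
  out <- deSolve::lsoda(0.6, c(0, 2), rhs, parms = NULL, rtol = 1e-10)
  expect_equal(unname(out[2, 2]), p0$activation_min, tolerance = 1e-4)
})

test_that("activation rises monotonically toward its fixed point without overshoot", {
  rhs <- function(t, y, p) list(activation_rate(y, 1, p0$l_ce_opt, p0))
  tt <- seq(0, 1, by = 0.005)
  out <- deSolve::lsoda(p0$activation_min, tt, rhs, parms = NULL, rtol = 1e-9)
  a <- out[, 2]
  a_inf <- activation_fixed_point(1, 1, p0)
  expect_true(all(diff(a) >= -1e-12))
  expect_true(all(a <= a_inf + 1e-9))
  expect_equal(a[length(a)], a_inf, tolerance = 1e-4)
})

test_that("stronger stimulation gives pointwise larger activity (comparison principle)", {
  tt <- seq(0, 0.6, by = 0.005)
  sol <- function(u) {
    rhs <- function(t, y, p) list(activation_rate(y, u, p0$l_ce_opt, p0))
    deSolve::lsoda(0.02, tt, rhs, parms = NULL, rtol = 1e-9)[, 2]
  }
  expect_true(all(sol(0.3) <= sol(0.7) + 1e-10))
})

test_that("activation stays within [a_min, 1] for arbitrary bounded stimulation", {
  set.seed(3)
  u_of_t <- stats::approxfun(seq(0, 1, by = 0.05), runif(21), rule = 2)
  rhs <- function(t, y, p) list(activation_rate(y, u_of_t(t), 0.9 * p0$l_ce_opt, p0))
  out <- deSolve::lsoda(0.5, seq(0, 1, by = 0.01), rhs, parms = NULL, rtol = 1e-8)
  expect_true(all(out[, 2] >= p0$activation_min - 1e-9))
  expect_true(all(out[, 2] <= 1))
})

test_that("full-activity isometric force at optimal fiber length reaches f_max within 2%", {
  # pick the path length whose isometric equilibrium puts the CE at l_ce_opt
  f <- function(l_mtu) isometric_equilibrium(l_mtu, 1, p0)$l_ce - p0$l_ce_opt
  l_star <- stats::uniroot(f, c(p0$see_rest_length + 0.9 * p0$l_ce_opt,
                                p0$see_rest_length + 1.2 * p0$l_ce_opt),
                           tol = 1e-10)$root
  eq <- isometric_equilibrium(l_star, 1, p0)
  expect_equal(eq$force, p0$f_max, tolerance = 0.02)
})

test_that("passive state carries (almost) no force when the tendon is slack", {
  l_mtu <- p0$see_rest_length + p0$l_ce_opt
  eq <- isometric_equilibrium(l_mtu, 0, p0)
  expect_lt(eq$force, 0.02 * p0$f_max)
})

test_that("steady-state internal equilibrium residual is below 1e-8 f_max", {
  for (l_mtu in c(0.205, 0.215, 0.225)) {
    eq <- isometric_equilibrium(l_mtu, 0.4, p0)
    fr <- mtu_force(l_mtu, 0, eq$l_ce, eq$activity, p0)
    resid <- fr$f_ce + fr$f_pee - fr$f_see
    expect_lt(abs(resid), 1e-8 * p0$f_max)
    expect_lt(abs(fr$v_ce), 1e-9)
  }
})

test_that("CE force is non-increasing with shortening velocity and exceeds isometric when lengthening", {
  l_mtu <- p0$see_rest_length + p0$l_ce_opt * 1.01
  eq <- isometric_equilibrium(l_mtu, 0.6, p0)
  vv <- seq(-0.4, 0.4, by = 0.02)
  f <- vapply(vv, function(v)
    mtu_force(l_mtu, v, eq$l_ce, eq$activity, p0)$f_ce, numeric(1))
  expect_true(all(diff(f) >= -1e-9))
  f0 <- mtu_force(l_mtu, 0, eq$l_ce, eq$activity, p0)$f_ce
  expect_true(all(f[vv > 0.05] > f0))
  expect_true(all(f[vv < -0.05] < f0))
})

test_that("CE force collapses when the fiber shortens rapidly into a slack tendon", {
  # tendon just slack: the force balance drives the CE to shorten near its
  # maximal velocity, where the Hill hyperbola lets the force fall to ~0
  l_mtu <- 0.99 * p0$see_rest_length + p0$l_ce_opt
  f <- mtu_force(l_mtu, 0, p0$l_ce_opt, 1, p0)
  expect_lt(f$f_ce, 0.05 * p0$f_max)
  expect_lt(f$v_ce, -0.05)
})

test_that("isometric force-length curve is unimodal with its maximum at l_ce_opt", {
  lrel <- seq(0.5, 1.6, by = 0.01)
  f <- vapply(lrel, function(l) nmsarm:::fl_isom(l, p0), numeric(1))
  i <- which.max(f)
  expect_equal(lrel[i], 1, tolerance = 0.011)
  expect_true(all(diff(f[lrel <= 1]) >= 0))
  expect_true(all(diff(f[lrel >= 1]) <= 0))
})

test_that("a lengthening step raises the tendon force within the same step (preflex)", {
  l_mtu <- p0$see_rest_length + p0$l_ce_opt * 1.02
  eq <- isometric_equilibrium(l_mtu, 0.3, p0)
  f0 <- mtu_force(l_mtu, 0, eq$l_ce, eq$activity, p0)$force
  f1 <- mtu_force(l_mtu + 5e-4, 0.05, eq$l_ce, eq$activity, p0)$force
  expect_gt(f1, f0)
})

test_that("the closed-form CE velocity solves the raw force balance (root-finding oracle)", {
  set.seed(11)
  model <- test_model()
  P <- model$P
  worst <- 0
  for (k in 1:200) {
    phi <- runif(1, 0.5, 1.6)
    omega <- runif(1, -4, 4)
    lce <- P$l_opt * runif(4, 0.8, 1.2)
    act <- runif(4, 0.005, 1)
    lmtu <- vapply(seq_len(4), function(i)
      model$routing[[i]]$length(phi), numeric(1))
    r <- vapply(seq_len(4), function(i)
      model$routing[[i]]$moment_arm(phi), numeric(1))
    fr <- nmsarm:::fast_force(lmtu, -r * omega, lce, act, P)
    for (i in 1:4) {
      s <- mtu_force(lmtu[i], -r[i] * omega, lce[i], act[i],
                     model$muscles[[i]]$params)
      worst <- max(worst, abs(s$v_ce - fr$v_ce[i]),
                   abs(s$force - fr$force[i]) / P$f_max[i])
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("parameter invariants are enforced", {
  expect_error(mtu_params(-1, 0.1, 0.1), "positive")
  expect_error(mtu_params(100, 0.1, 0.1, activation_min = 1.2), "activation_min")
  expect_error(mtu_params(100, 0.1, 0.1, ecc_force_factor = 0.9), "ecc_force_factor")
})
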