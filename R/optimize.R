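# Derivative-free optimizers for controller calibration: a small Gaussian-
# process Bayesian optimizer (expected-improvement acquisition) for the
# acceleration-phase parameters, and a Hooke-Jeeves pattern search for the
# feedback-gain calibration. Both are deterministic given the seed.

#' Seeded Bayesian optimization (GP + expected improvement)
#'
#' Minimizes a black-box function over a box. A space-filling initial design
#' is followed by expected-improvement steps under a Gaussian-process
#' surrogate (squared-exponential kernel on inputs normalized to the unit
#' box, fixed relative lengthscale). Non-finite objective values are treated
#' as rejected candidates (assigned a large penalty) and logged.
#'
#' @param fn objective function of a numeric vector, returning a scalar
#' @param lower,upper box bounds
#' @param budget total number of function evaluations
#' @param n_init size of the initial Latin-hypercube design
#' @param seed RNG seed; the whole run is reproducible given it
#' @param candidates number of acquisition candidates per iteration
#' @param lengthscale GP kernel lengthscale in normalized units
#' @return list with `par`, `value`, the evaluated `X` matrix and `y` vector,
#'   and `n_rejected`
#' @export
bayes_opt <- function(fn, lower, upper, budget = 60, n_init = 10, seed = 1,
                      candidates = 400, lengthscale = 0.25) {
  stopifnot(length(lower) == length(upper), all(upper > lower),
            budget > n_init)
  d <- length(lower)
  set.seed(seed)
  scale_up <- function(U) sweep(sweep(U, 2, upper - lower, "*"), 2, lower, "+")
  X <- scale_up(lhs::randomLHS(n_init, d))
  penalty <- NULL
  n_rejected <- 0
  eval1 <- function(x) {
    v <- tryCatch(fn(x), error = function(e) NA_real_)
    if (!is.finite(v)) {
      n_rejected <<- n_rejected + 1
      return(NA_real_)
    }
    v
  }
  y <- apply(X, 1, eval1)
  fill <- function(yv) {
    # rejected candidates get a value worse than anything observed
    if (all(is.na(yv))) stop("all initial candidates failed")
    bad <- is.na(yv)
    sdv <- stats::sd(yv[!bad])
    if (!is.finite(sdv) || sdv == 0) sdv <- max(abs(yv[!bad]), 1)
    yv[bad] <- max(yv, na.rm = TRUE) + 10 * sdv + 1
    yv
  }
  while (nrow(X) < budget) {
    yf <- fill(y)
    U <- sweep(sweep(X, 2, lower, "-"), 2, upper - lower, "/")
    mu_y <- mean(yf); sd_y <- stats::sd(yf)
    if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
    z <- (yf - mu_y) / sd_y
    K <- exp(-0.5 * as.matrix(stats::dist(U))^2 / lengthscale^2)
    diag(K) <- diag(K) + 1e-8
    L <- tryCatch(chol(K), error = function(e) {
      diag(K) <- diag(K) + 1e-4
      chol(K)
    })
    alpha <- backsolve(L, forwardsolve(t(L), z))
    # candidate set: fresh LHS plus local jitter around the incumbent
    Uc <- rbind(lhs::randomLHS(candidates, d),
                matrix(pmin(pmax(rep(U[which.min(yf), ], each = 40) +
                                   stats::rnorm(40 * d, 0, 0.03), 0), 1),
                       ncol = d))
    Kc <- exp(-0.5 * crossdist2(Uc, U) / lengthscale^2)
    mu <- drop(Kc %*% alpha)
    vK <- forwardsolve(t(L), t(Kc))
    s2 <- pmax(1 - colSums(vK^2), 1e-12)
    s <- sqrt(s2)
    ybest <- min(z)
    imp <- ybest - mu
    ei <- imp * stats::pnorm(imp / s) + s * stats::dnorm(imp / s)
    ei[!is.finite(ei)] <- -Inf
    pick <- if (all(ei == -Inf)) sample.int(nrow(Uc), 1) else which.max(ei)
    xn <- scale_up(Uc[pick, , drop = FALSE])
    X <- rbind(X, xn)
    y <- c(y, eval1(drop(xn)))
  }
  yf <- fill(y)
  best <- which.min(yf)
  list(par = drop(X[best, ]), value = yf[best], X = X, y = y,
       n_rejected = n_rejected)
}

# squared Euclidean cross-distances between row sets
crossdist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  outer(an, bn, "+") - 2 * A %*% t(B)
}

#' Hooke-Jeeves pattern search
#'
#' Deterministic coordinate pattern search with step halving, used for the
#' feedback-gain calibration.
#'
#' @param fn objective function
#' @param x0 start point
#' @param step initial step sizes (same length as `x0`)
#' @param lower,upper box bounds
#' @param budget maximum number of function evaluations
#' @param shrink step-halving factor on failure
#' @param min_step stop when all steps fall below this fraction of the range
#' @return list with `par`, `value`, `evals`
#' @export
pattern_search <- function(fn, x0, step, lower, upper, budget = 40,
                           shrink = 0.5, min_step = 1e-3) {
  clamp <- function(x) pmin(pmax(x, lower), upper)
  x <- clamp(x0)
  evals <- 0
  fx <- fn(x); evals <- evals + 1
  rng <- upper - lower
  while (evals < budget && any(step > min_step * rng)) {
    improved <- FALSE
    for (i in seq_along(x)) {
      for (s in c(1, -1)) {
        if (evals >= budget) break
        xt <- x; xt[i] <- xt[i] + s * step[i]
        xt <- clamp(xt)
        if (all(xt == x)) next
        ft <- fn(xt); evals <- evals + 1
        if (is.finite(ft) && ft < fx) {
          x <- xt; fx <- ft; improved <- TRUE
          break
        }
      }
    }
    if (!improved) step <- step * shrink
  }
  list(par = x, value = fx, evals = evals)
}

#' Optimize the acceleration phase of the triphasic pattern
#'
#' Seeded Bayesian optimization of the agonist acceleration stimulation
#' `u_acc` and the switching time `t1`, minimizing the mean squared pointwise
#' difference (in degrees) between the simulated open-loop trajectory and the
#' minimum-jerk desired trajectory. Candidates whose simulation fails (e.g.,
#' leaves the anatomical range) are rejected.
#'
#' @param model an `nms_model`
#' @param plan a [movement_plan()]
#' @param pattern_skeleton a [triphasic_pattern()] carrying the pre-solved
#'   `u0`, `u_dec`, `u_final`, `u_min`, `t2` and agonist set; its `u_acc`/`t1`
#'   are overwritten during the search
#' @param pert steady perturbation context of the movement (for the dynamic
#'   protocol this carries the constant bias torque)
#' @param budget,n_init,seed Bayesian-optimization settings
#' @param horizon,rtol simulation settings
#' @return list with `u_acc`, `t1`, `objective` (deg^2), `pattern`, `bo`
#' @export
optimize_acceleration_phase <- function(model, plan, pattern_skeleton,
                                        pert = perturbation("none"),
                                        budget = 60, n_init = 10, seed = 1,
                                        horizon = 1, rtol = 1e-5) {
  sk <- pattern_skeleton
  cfg <- model$config$controller$optimization
  t1_lo <- plan$onset + cfg$t1_frac_bounds[1] * (sk$t2 - plan$onset)
  t1_hi <- plan$onset + cfg$t1_frac_bounds[2] * (sk$t2 - plan$onset)
  lower <- c(cfg$u_acc_bounds[1], t1_lo)
  upper <- c(cfg$u_acc_bounds[2], t1_hi)
  grid <- seq(0, horizon, by = 1e-3)
  des <- desired_trajectory(grid, plan)$angle * 180 / pi
  obj <- function(x) {
    pat <- triphasic_pattern(sk$u0, x[1], sk$u_min, sk$u_dec, sk$u_final,
                             x[2], sk$t2, sk$agonists, onset = sk$onset)
    res <- simulate_movement(model, pat, plan, pert = pert, horizon = horizon,
                             rtol = rtol, diagnostics = FALSE)
    mean((res$phi * 180 / pi - des)^2)
  }
  bo <- bayes_opt(obj, lower, upper, budget = budget, n_init = n_init,
                  seed = seed)
  pat <- triphasic_pattern(sk$u0, bo$par[1], sk$u_min, sk$u_dec, sk$u_final,
                           bo$par[2], sk$t2, sk$agonists, onset = sk$onset)
  list(u_acc = bo$par[1], t1 = bo$par[2], objective = bo$value,
       pattern = pat, bo = bo)
}

#' Calibrate the full controller for a movement
#'
#' Runs the calibration pipeline: (1) equilibrium stimulations for the start,
#' final and braking phases; (2) Bayesian optimization of the acceleration
#' phase; (3) recording of the unperturbed reference (fiber lengths and
#' velocities); (4) optionally, pattern-search calibration of the feedback
#' gains and the braking co-contraction level against a table of
#' perturbation-response statistics. During the gain search the
#' acceleration-phase parameters are held fixed; if the braking
#' co-contraction changed, the acceleration phase is re-optimized once at the
#' end and the reference re-recorded.
#'
#' @param model an `nms_model`
#' @param plan a [movement_plan()]; default from the model config
#' @param delay feedback delay (s)
#' @param bias_torque constant bias torque of the movement context (N m)
#' @param calibrate_gains run the gain calibration (slow); otherwise the
#'   supplied/config gains and braking co-contraction are used as-is
#' @param gains optional list with `k_p`, `k_d` overriding the config values
#'   (used to transfer calibrated gains to a re-calibration for another
#'   movement context)
#' @param u_des_dec optional braking co-contraction level override
#' @param reference_table experimental-reference table for the gain
#'   calibration cost (see [cost_eq5()]); default the packaged synthetic table
#' @param seed seed for the optimization stages
#' @param bo_budget,bo_init Bayesian-optimization budget
#' @param gain_budget pattern-search budget (objective evaluations)
#' @param horizon,rtol simulation settings
#' @return object of class `nms_calibration`
#' @export
calibrate_controller <- function(model, plan = NULL, delay = 0.05,
                                 bias_torque = 0, calibrate_gains = TRUE,
                                 gains = NULL, u_des_dec = NULL,
                                 reference_table = NULL, seed = 1,
                                 bo_budget = NULL, bo_init = NULL,
                                 gain_budget = NULL, horizon = 1,
                                 rtol = NULL) {
  cc <- model$config$controller
  if (is.null(plan)) {
    pc <- model$config$plan
    plan <- movement_plan(pc$start_deg * pi / 180, pc$end_deg * pi / 180,
                          onset = pc$onset, duration = pc$duration)
  }
  if (is.null(bo_budget)) bo_budget <- cc$optimization$budget
  if (is.null(bo_init)) bo_init <- cc$optimization$init
  if (is.null(gain_budget)) gain_budget <- cc$gain_search$budget
  if (is.null(rtol)) rtol <- model$config$solver$rtol
  if (is.null(u_des_dec)) u_des_dec <- cc$u_des_dec
  k_p <- if (is.null(gains)) cc$feedback$k_p else gains$k_p
  k_d <- if (is.null(gains)) cc$feedback$k_d else gains$k_d
  agonists <- agonist_set(model, plan)
  pert_ctx <- perturbation("none", constant_torque = bias_torque)

  build_pattern <- function(udd, u_acc = 0.2, t1 = NULL) {
    eq0 <- solve_equilibrium_stimulations(model, plan$start_angle,
                                          u_des = cc$u_des_hold,
                                          external_torque = bias_torque)
    eqf <- solve_equilibrium_stimulations(model, plan$end_angle,
                                          u_des = cc$u_des_hold,
                                          external_torque = bias_torque)
    eqd <- solve_equilibrium_stimulations(model, plan$end_angle,
                                          u_des = udd,
                                          external_torque = bias_torque)
    if (is.null(t1)) t1 <- (plan$onset + cc$t2) / 2
    list(pattern = triphasic_pattern(eq0$u, u_acc, cc$u_min, eqd$u, eqf$u,
                                     t1, cc$t2, agonists, onset = plan$onset),
         eq0 = eq0, eqf = eqf, eqd = eqd)
  }
  record <- function(pattern) {
    rec <- simulate_movement(model, pattern, plan,
                             feedback = feedback_config(0, 0, delay,
                                                        enabled = FALSE),
                             pert = pert_ctx, horizon = horizon, rtol = rtol)
    list(rec = rec, reference = record_reference(rec, delay = delay))
  }
  calibrate_once <- function(udd) {
    bp <- build_pattern(udd)
    acc <- optimize_acceleration_phase(model, plan, bp$pattern,
                                       pert = pert_ctx, budget = bo_budget,
                                       n_init = bo_init, seed = seed,
                                       horizon = horizon, rtol = rtol)
    c(list(bp = bp, acc = acc), record(acc$pattern))
  }

  base <- calibrate_once(u_des_dec)
  gains_trace <- NULL
  if (calibrate_gains) {
    if (is.null(reference_table)) reference_table <- synthetic_reference_table()
    gs <- cc$gain_search
    # the open-loop pattern and reference depend only on the braking
    # co-contraction; cache them and keep (u_acc, t1) fixed in the search
    cache <- new.env(parent = emptyenv())
    assign(format(u_des_dec, digits = 15), base, envir = cache)
    get_cal <- function(udd) {
      key <- format(udd, digits = 15)
      if (is.null(cache[[key]])) {
        bp <- build_pattern(udd, u_acc = base$acc$u_acc, t1 = base$acc$t1)
        cache[[key]] <- c(list(bp = bp, acc = base$acc), record(bp$pattern))
      }
      cache[[key]]
    }
    obj <- function(x) {
      cal <- get_cal(x[3])
      fb <- feedback_config(x[1], x[2], delay)
      pat <- if (is.null(cal$bp)) cal$acc$pattern else {
        triphasic_pattern(cal$bp$eq0$u, base$acc$u_acc, cc$u_min,
                          cal$bp$eqd$u, cal$bp$eqf$u, base$acc$t1, cc$t2,
                          agonists, onset = plan$onset)
      }
      mt <- tryCatch(
        static_metrics(model, pat, plan, fb, cal$reference,
                       ref_run = cal$rec, horizon = horizon, rtol = rtol),
        error = function(e) NULL)
      if (is.null(mt)) return(Inf)
      cost_eq5(mt, reference_table)
    }
    ps <- pattern_search(
      obj, x0 = c(k_p, k_d, u_des_dec),
      step = c(diff(gs$k_p_bounds), diff(gs$k_d_bounds),
               diff(gs$u_des_dec_bounds)) / 4,
      lower = c(gs$k_p_bounds[1], gs$k_d_bounds[1], gs$u_des_dec_bounds[1]),
      upper = c(gs$k_p_bounds[2], gs$k_d_bounds[2], gs$u_des_dec_bounds[2]),
      budget = gain_budget)
    k_p <- ps$par[1]; k_d <- ps$par[2]
    gains_trace <- ps
    if (abs(ps$par[3] - u_des_dec) > 1e-12) {
      u_des_dec <- ps$par[3]
      base <- calibrate_once(u_des_dec)
    }
  }

  structure(list(
    plan = plan, delay = delay, bias_torque = bias_torque,
    pattern = base$acc$pattern, reference = base$reference,
    recording = base$rec,
    feedback = feedback_config(k_p, k_d, delay),
    u_des_dec = u_des_dec,
    equilibria = list(start = base$bp$eq0, final = base$bp$eqf,
                      braking = base$bp$eqd),
    bo = base$acc$bo, objective = base$acc$objective,
    gains_trace = gains_trace, seed = seed, horizon = horizon, rtol = rtol),
    class = "nms_calibration")
}

#' @export
print.nms_calibration <- function(x, ...) {
  cat(sprintf(
    "<nms_calibration> %s, delay %.0f ms | u_acc=%.3f t1=%.3f s | kp=%.2f kd=%.3f | RMS obj %.3f deg^2\n",
    if (x$plan$end_angle >= x$plan$start_angle) "flexion" else "extension",
    x$delay * 1000, x$pattern$u_acc, x$pattern$t1,
    x$feedback$k_p, x$feedback$k_d, x$objective))
  invisible(x)
}
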