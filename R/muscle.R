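# Four-element Hill-type muscle-tendon unit (MTU): contractile element (CE)
# with force-length-velocity properties, parallel elastic element (PEE),
# non-linear/linear serial elastic element (SEE) and serial damping element
# (SDE), plus Hatze-style activation dynamics with fiber-length dependence.
# The CE contraction velocity is obtained each step from the internal force
# balance CE + PEE = SEE + SDE; multiplying the balance by the Hill-hyperbola
# denominator makes it exactly quadratic in the velocity, which is solved in
# closed form.

#' Muscle-tendon unit parameters
#'
#' All constants of the four-element Hill-type model and of the activation
#' dynamics. Defaults are generic values in the range of the elbow-muscle
#' literature; any published parameter set can be dropped in via the config.
#'
#' @param f_max maximal isometric force (N)
#' @param l_ce_opt optimal CE length (m)
#' @param see_rest_length SEE rest (slack) length (m)
#' @param fl_width width of the isometric force-length bell (dimensionless,
#'   relative to `l_ce_opt`)
#' @param fl_exponent exponent of the force-length bell
#' @param hill_a_rel,hill_b_rel normalized Hill constants (a_rel
#'   dimensionless, b_rel 1/s)
#' @param ecc_force_factor asymptotic eccentric force as a multiple of the
#'   isometric force (> 1)
#' @param ecc_slope_factor ratio of eccentric to concentric force-velocity
#'   slope at zero velocity (> 0)
#' @param see_nonlinear_strain relative SEE strain at the end of the
#'   non-linear toe region
#' @param see_linear_strain relative strain scale of the linear region
#'   (sets the linear stiffness)
#' @param see_force_at_transition_rel SEE force at the toe-to-linear
#'   transition, relative to `f_max`
#' @param pee_slack_rel PEE slack length relative to `l_ce_opt`
#' @param pee_exponent PEE exponent
#' @param pee_force_factor PEE force (relative to `f_max`) at
#'   `l_ce_opt * (1 + fl_width)`
#' @param serial_damping_coeff maximal SDE damping, normalized (dimensionless
#'   D_se; the dimensional coefficient is
#'   `D_se * f_max * hill_a_rel / (hill_b_rel * l_ce_opt)`)
#' @param serial_damping_min_rel force-independent share of the SDE damping
#' @param activation_min lower bound of the activity (0 < a_min < 1)
#' @param activation_rate_const rate constant of the activation dynamics (1/s)
#' @param hatze_nu exponent of the Hatze non-linearity
#' @param hatze_rho_c scale of the Hatze length dependence (dimensionless)
#' @param hatze_l_rho pole length of the Hatze length dependence (relative to
#'   `l_ce_opt`)
#' @return object of class `mtu_params`
#' @export
mtu_params <- function(f_max, l_ce_opt, see_rest_length,
                       fl_width = 0.35, fl_exponent = 2,
                       hill_a_rel = 0.25, hill_b_rel = 2.25,
                       ecc_force_factor = 1.5, ecc_slope_factor = 2,
                       see_nonlinear_strain = 0.02,
                       see_linear_strain = 0.012,
                       see_force_at_transition_rel = 0.4,
                       pee_slack_rel = 1.0, pee_exponent = 2.5,
                       pee_force_factor = 2,
                       serial_damping_coeff = 0.3,
                       serial_damping_min_rel = 0.01,
                       activation_min = 0.005,
                       activation_rate_const = 11.3,
                       hatze_nu = 3, hatze_rho_c = 5.9, hatze_l_rho = 2.9) {
  p <- as.list(environment())
  if (f_max <= 0 || l_ce_opt <= 0 || see_rest_length <= 0)
    stop("f_max, l_ce_opt and see_rest_length must be strictly positive")
  if (activation_min <= 0 || activation_min >= 1)
    stop("activation_min must lie in (0, 1)")
  if (ecc_force_factor <= 1) stop("ecc_force_factor must exceed 1")
  stopifnot(fl_width > 0, hill_a_rel > 0, hill_b_rel > 0,
            see_nonlinear_strain > 0, see_linear_strain > 0)
  structure(p, class = "mtu_params")
}

# isometric force-length bell, maximal (=1) at l_ce_opt
fl_isom <- function(lrel, p) {
  exp(-abs((lrel - 1) / p$fl_width)^p$fl_exponent)
}

f_pee <- function(l_ce, p) {
  slack <- p$pee_slack_rel * p$l_ce_opt
  k <- p$pee_force_factor * p$f_max /
    (p$l_ce_opt * (p$fl_width + 1 - p$pee_slack_rel))^p$pee_exponent
  ifelse(l_ce > slack, k * (l_ce - slack)^p$pee_exponent, 0)
}

f_see <- function(l_see, p) {
  l0 <- p$see_rest_length
  du_nll <- p$see_nonlinear_strain
  du_l <- p$see_linear_strain
  df0 <- p$see_force_at_transition_rel * p$f_max
  nu <- du_nll / du_l                 # makes the toe C1-continuous
  l_nll <- (1 + du_nll) * l0
  k_lin <- df0 / (du_l * l0)
  out <- numeric(length(l_see))
  toe <- l_see > l0 & l_see <= l_nll
  lin <- l_see > l_nll
  out[toe] <- df0 * ((l_see[toe] - l0) / (du_nll * l0))^nu
  out[lin] <- df0 + k_lin * (l_see[lin] - l_nll)
  out
}

# Hatze length dependence of the activation fixed point
hatze_rho <- function(lrel, p) {
  lr <- pmin(pmax(lrel, 0.4), 0.999 * p$hatze_l_rho)
  p$hatze_rho_c * (p$hatze_l_rho - 1) / (p$hatze_l_rho / lr - 1)
}

#' Activation fixed point
#'
#' Steady-state muscle activity for a held stimulation at a given fiber
#' length (Hatze non-linearity): increases monotonically with stimulation and
#' with fiber length, bounded in `[activation_min, 1)`.
#'
#' @param stimulation neural stimulation in `[0, 1]`
#' @param lrel CE length relative to `l_ce_opt`
#' @param p an [mtu_params()]
#' @return steady-state activity
#' @export
activation_fixed_point <- function(stimulation, lrel, p) {
  x <- (hatze_rho(lrel, p) * stimulation)^p$hatze_nu
  (p$activation_min + x) / (1 + x)
}

#' Activation dynamics rate
#'
#' First-order dynamics of the muscle activity toward the stimulation- and
#' fiber-length-dependent fixed point.
#'
#' @param activity current activity
#' @param stimulation neural stimulation in `[0, 1]` (pre-clipped)
#' @param l_ce CE length (m)
#' @param p an [mtu_params()]
#' @return time derivative of the activity (1/s)
#' @export
activation_rate <- function(activity, stimulation, l_ce, p) {
  p$activation_rate_const *
    (activation_fixed_point(stimulation, l_ce / p$l_ce_opt, p) - activity)
}

# Hill force-velocity setup at the current activity/length
hill_setup <- function(lrel, q, p) {
  fisom <- fl_isom(lrel, p)
  l_a <- ifelse(lrel < 1, 1, fisom)   # descending-limb scaling of a_rel
  a_rel <- p$hill_a_rel * l_a * (1 + 3 * q) / 4
  b_rel <- p$hill_b_rel * (3 + 4 * q) / 7
  list(fisom = fisom, a_rel = a_rel, b = b_rel * p$l_ce_opt)
}

# solve a v-quadratic g(v) = a0 + a1 v + a2 v^2 = 0 given evaluations of g at
# 0, +h, -h; returns the root where g'(root) > 0 (the physical branch), NA if
# the discriminant is negative
quad_root_positive_slope <- function(g0, gp, gm, h) {
  a0 <- g0
  a1 <- (gp - gm) / (2 * h)
  a2 <- (gp + gm - 2 * g0) / (2 * h^2)
  if (abs(a2) < 1e-12 * max(1, abs(a1))) {
    if (a1 == 0) return(NA_real_)
    return(if (a1 > 0) -a0 / a1 else NA_real_)
  }
  disc <- a1^2 - 4 * a0 * a2
  if (disc < 0) return(NA_real_)
  sq <- sqrt(disc)
  r1 <- (-a1 - sq) / (2 * a2)
  r2 <- (-a1 + sq) / (2 * a2)
  lo <- min(r1, r2); hi <- max(r1, r2)
  if (a2 > 0) hi else lo
}

# internal force balance residual at CE velocity v (scalars)
mtu_residual <- function(v, l_mtu, v_mtu, l_ce, q, p, hs, f_p, f_s) {
  lrel <- l_ce / p$l_ce_opt
  conc <- v <= 0
  if (conc) {
    c1 <- q * hs$fisom + hs$a_rel
    f_ce <- p$f_max * (c1 / (1 - v / hs$b) - hs$a_rel)
  } else {
    a_e <- -p$ecc_force_factor * q * hs$fisom
    b_e <- q * hs$fisom * (1 - p$ecc_force_factor) * hs$b /
      (p$ecc_slope_factor * (q * hs$fisom + hs$a_rel))
    f_ce <- p$f_max * ((q * hs$fisom + a_e) / (1 - v / b_e) - a_e)
  }
  d_max <- p$serial_damping_coeff * p$f_max * p$hill_a_rel /
    (p$hill_b_rel * p$l_ce_opt)
  r <- p$serial_damping_min_rel
  f_sde <- d_max * ((1 - r) * (f_ce + f_p) / p$f_max + r) * (v_mtu - v)
  f_ce + f_p - f_s - f_sde
}

#' Muscle-tendon unit force and fiber velocity
#'
#' Solves the internal force balance between CE + PEE and SEE + SDE for the
#' CE contraction velocity and returns the tendon force transmitted to the
#' bone. Concentric and eccentric Hill branches are handled separately; each
#' reduces to a closed-form quadratic.
#'
#' @param l_mtu total muscle-tendon path length (m)
#' @param v_mtu path lengthening velocity (m/s)
#' @param l_ce CE length (m)
#' @param activity muscle activity in `[activation_min, 1]`
#' @param p an [mtu_params()]
#' @return list with `force` (N, tendon force), `v_ce` (m/s, CE lengthening
#'   velocity), and the element forces `f_ce`, `f_pee`, `f_see`, `f_sde`
#' @export
mtu_force <- function(l_mtu, v_mtu, l_ce, activity, p) {
  if (l_mtu <= 0) stop("l_mtu must be positive")
  q <- min(max(activity, p$activation_min), 1)
  lrel <- l_ce / p$l_ce_opt
  hs <- hill_setup(lrel, q, p)
  f_p <- f_pee(l_ce, p)
  f_s <- f_see(l_mtu - l_ce, p)
  d_max <- p$serial_damping_coeff * p$f_max * p$hill_a_rel /
    (p$hill_b_rel * p$l_ce_opt)
  r <- p$serial_damping_min_rel
  c1 <- q * hs$fisom + hs$a_rel

  # concentric branch: g(v) = residual(v) * (1 - v/b) is quadratic in v
  gc <- function(v) {
    f_ce <- p$f_max * (c1 / (1 - v / hs$b) - hs$a_rel)
    f_sde <- d_max * ((1 - r) * (f_ce + f_p) / p$f_max + r) * (v_mtu - v)
    (f_ce + f_p - f_s - f_sde) * (1 - v / hs$b)
  }
  h <- hs$b / 2
  v <- quad_root_positive_slope(gc(0), gc(h), gc(-h), h)
  branch <- "concentric"
  if (is.na(v) || v > 1e-12 || v >= hs$b) {
    a_e <- -p$ecc_force_factor * q * hs$fisom
    b_e <- q * hs$fisom * (1 - p$ecc_force_factor) * hs$b /
      (p$ecc_slope_factor * c1)
    c1e <- q * hs$fisom + a_e
    ge <- function(v) {
      f_ce <- p$f_max * (c1e / (1 - v / b_e) - a_e)
      f_sde <- d_max * ((1 - r) * (f_ce + f_p) / p$f_max + r) * (v_mtu - v)
      (f_ce + f_p - f_s - f_sde) * (1 - v / b_e)
    }
    he <- abs(b_e) / 2
    ve <- quad_root_positive_slope(ge(0), ge(he), ge(-he), he)
    if (!is.na(ve) && ve >= -1e-12) {
      v <- max(ve, 0)
      branch <- "eccentric"
    } else if (!is.na(v) && v <= 1e-9) {
      v <- min(v, 0)
    } else {
      # fall back to bracketed root-finding on the raw residual
      res <- function(vv) mtu_residual(vv, l_mtu, v_mtu, l_ce, q, p, hs, f_p, f_s)
      br <- tryCatch(
        stats::uniroot(res, lower = -0.99 * hs$b, upper = 5 * hs$b,
                       tol = 1e-12),
        error = function(e) NULL)
      if (is.null(br))
        stop(sprintf(
          "no root of the internal force balance: l_mtu=%.5f v_mtu=%.5f l_ce=%.5f q=%.4f",
          l_mtu, v_mtu, l_ce, q))
      v <- br$root
      branch <- if (v <= 0) "concentric" else "eccentric"
    }
  } else {
    v <- min(v, 0)
  }

  if (branch == "concentric") {
    f_ce <- p$f_max * (c1 / (1 - v / hs$b) - hs$a_rel)
  } else {
    a_e <- -p$ecc_force_factor * q * hs$fisom
    b_e <- q * hs$fisom * (1 - p$ecc_force_factor) * hs$b /
      (p$ecc_slope_factor * c1)
    f_ce <- p$f_max * ((q * hs$fisom + a_e) / (1 - v / b_e) - a_e)
  }
  f_sde <- d_max * ((1 - r) * (f_ce + f_p) / p$f_max + r) * (v_mtu - v)
  list(force = f_s + f_sde, v_ce = v,
       f_ce = f_ce, f_pee = f_p, f_see = f_s, f_sde = f_sde)
}

#' Isometric MTU equilibrium
#'
#' Finds the CE length at which, for a held stimulation and zero path
#' velocity, the steady-state activity and the internal force balance are
#' simultaneously satisfied. Used for equilibrium starts and initial states.
#'
#' @param l_mtu total path length (m)
#' @param stimulation held stimulation in `[0, 1]`
#' @param p an [mtu_params()]
#' @return list with `l_ce` (m), `activity`, and `force` (N)
#' @export
isometric_equilibrium <- function(l_mtu, stimulation, p) {
  resid <- function(l_ce) {
    q <- activation_fixed_point(stimulation, l_ce / p$l_ce_opt, p)
    hs <- hill_setup(l_ce / p$l_ce_opt, q, p)
    p$f_max * q * hs$fisom + f_pee(l_ce, p) - f_see(l_mtu - l_ce, p)
  }
  lo <- 0.25 * p$l_ce_opt
  hi <- l_mtu - 0.9 * p$see_rest_length
  if (hi <= lo || resid(lo) >= 0 || resid(hi) <= 0)
    stop(sprintf(
      "no isometric equilibrium in bracket for l_mtu=%.4f (tendon slack or path too short)",
      l_mtu))
  root <- stats::uniroot(resid, lower = lo, upper = hi, tol = 1e-12)$root
  q <- activation_fixed_point(stimulation, root / p$l_ce_opt, p)
  list(l_ce = root, activity = q, force = f_see(l_mtu - root, p))
}
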