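---
title: "A neuro-musculoskeletal model of perturbed elbow movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neuro-musculoskeletal model of perturbed elbow movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nmsarm` simulates goal-directed single-joint elbow movements with a
physiologically structured model: a rigid forearm (the shoulder is locked),
four Hill-type muscle-tendon units routed around via-ellipses, Hatze-style
length-dependent activation dynamics, and a hybrid controller that combines
an optimized piecewise-constant (triphasic) open-loop stimulation pattern
with time-delayed proportional-derivative feedback on muscle-fiber length
and contraction velocity. This vignette documents the model equations, the
calibration pipeline, the numerical choices, and the limits of what the
simulation experiments can show.

## The plant

The shoulder is locked, so the upper arm is the ground segment and the only
degree of freedom is the elbow flexion angle $\varphi$ (zero at full
extension, flexion positive). The forearm obeys

$$ I\,\ddot\varphi \;=\; \tau_{\text{muscle}}(\varphi,\dot\varphi,\mathbf{a},\mathbf{l}_{CE})
   \;-\; (d_0 + \Delta d)\,\dot\varphi \;+\; \tau_{\text{bias}} \;+\; \tau_{\text{imp}}(t), $$

with total inertia $I = I_0 + \Delta I$. The deltas $\Delta I$ and
$\Delta d$ are the static perturbations an exoskeleton robot renders
continuously during a trial; $\tau_{\text{bias}}$ is a constant
gravity-mimicking torque ($-1.5$ N·m in the dynamic protocol) and
$\tau_{\text{imp}}$ a finite torque pulse ($\pm 5$ N·m for $37.5$ ms) fired
when 25% of the movement amplitude has been traversed. The impulse onset is
located by the integrator's root finder, never by fixed-step thresholding.

The default inertia about the elbow is $I_0 = 0.20$ kg·m², the sum of a
forearm-plus-hand contribution (about $0.09$ kg·m² for a 1.8 kg, 0.45 m
segment) and a comparable contribution from the exoskeleton arm the
experimental protocols attach to the limb. This value is constrained by the
impulse experiments themselves: a $\pm5$ N·m, 37.5 ms pulse must change a
$\sim\!75$°/s movement's velocity by roughly a factor of two, which fixes
the free rigid-body velocity change $\tau\,\Delta t/I$ near 1 rad/s once the
immediate muscular reaction is accounted for. Inertias much below
$\sim\!0.15$ kg·m² would let the against-movement impulse reverse the arm
outright, which is not what the perturbation experiments report.

## Muscle-tendon units

Each of the four MTUs (elbow flexor, elbow extensor, biarticular flexor,
biarticular extensor — the monoarticular shoulder muscles have no effect
with the shoulder locked and are omitted) is a four-element Hill-type model:
contractile element (CE), parallel elastic element (PEE), serial elastic
element (SEE) and serial damping element (SDE), with

* an isometric force-length bell
  $F_{isom}(\ell) = \exp(-|(\ell-1)/w|^{\nu_\ell})$, $\ell = l_{CE}/l_{CE,opt}$,
  width $w = 0.35$, exponent 2;
* a Hill force-velocity hyperbola with activation-scaled constants
  $a_{rel} \propto (1+3q)/4$, $b_{rel} \propto (3+4q)/7$
  ($a_{rel,0} = 0.25$, $b_{rel,0} = 2.25\,\mathrm{s}^{-1}$) and an eccentric
  branch constructed from the slope ratio at zero velocity
  (`ecc_slope_factor`, 2) and the eccentric force plateau
  (`ecc_force_factor`, 1.5);
* a PEE engaging at $l_{CE,opt}$ (exponent 2.5, reaching twice $F_{max}$ at
  $l_{CE,opt}(1+w)$);
* an SEE with a non-linear toe up to 2% strain and a linear region with a
  1.2% strain scale (about 3% total strain at $F_{max}$ — a stiff
  tendon-aponeurosis characteristic; see "Design choices" below);
* a force-dependent serial damping ($D_{SE} = 0.3$, $R_{SE} = 0.01$).

The CE velocity is not integrated against a stiff algebraic residual;
instead the internal force balance $F_{CE}+F_{PEE} = F_{SEE}+F_{SDE}$ is
solved in closed form at every evaluation of the right-hand side.
Multiplying the balance by the Hill-hyperbola denominator $1 - v/b$ makes it
exactly quadratic in $v = \dot l_{CE}$; the physical root is the one at
which the balance has positive slope, chosen per branch (concentric /
eccentric), with a bracketed root-finder as fallback for degenerate states.
The closed-form solution is verified against the root-finding route in the
test suite.

Activation follows first-order dynamics toward a stimulation- and
fiber-length-dependent fixed point built from the Hatze non-linearity,

$$ \dot a = m\,\big(a_\infty(u,\ell) - a\big), \qquad
   a_\infty = \frac{a_{min} + (\rho(\ell)\,u)^{\nu}}{1 + (\rho(\ell)\,u)^{\nu}},
   \qquad \rho(\ell) = \rho_c\,\frac{\ell_\rho - 1}{\ell_\rho/\ell - 1}, $$

with $m = 11.3\ \mathrm{s}^{-1}$, $\nu = 3$, $\rho_c = 5.9$,
$\ell_\rho = 2.9$ and $a_{min} = 0.005$. This keeps the documented state pair
$(l_{CE}, a)$ per muscle; the free-calcium concentration of the full Hatze
cascade is not carried as a separate state. All invariants that matter for
the controller hold: the fixed point rises monotonically with stimulation
and with fiber length, and the activity stays in $[a_{min}, 1]$.

## Muscle routing and internal loads

Muscle paths run in the plane of movement from an origin fixed to the upper
arm to an insertion fixed to the forearm, as the shortest route that does not
penetrate a set of ellipses fixed to the bones. Tangent points on an ellipse
are available in closed form (the tangency condition
$b\,p_x\cos\theta + a\,p_y\sin\theta = ab$ is a single phase-shifted
cosine), arcs are integrated with 24-node Gauss-Legendre quadrature, and
both wrap directions are compared to pick the shortest valid route. The
moment arm is the tendon-excursion definition
$r(\varphi) = -\partial L/\partial\varphi$, evaluated by
Richardson-extrapolated central differences of the exact path solver.
Inside the simulation right-hand side the four path lengths are read from a
cubic-spline interpolant over the anatomical range, and the moment arm is
the exact negative derivative *of that interpolant*, which makes the
joint-power balance $\tau\omega = \sum_i F_i(-\dot L_i)$ an identity of the
discretization.

The default geometry places olecranon-style insertions for the extensors
(proximally, behind the joint center) and trochlea-scale deflection ellipses
(2-3 cm semi-axes) at the elbow, tuned so flexor moment arms peak at 2-4 cm
in mid-flexion and extensor moment arms stay near $-2$ to $-3$ cm. With this
anatomy the flexor path wraps its ellipse near full extension and the
extensor wraps at deep flexion; in the default 45°-75° movement both paths
happen to run straight, so the reported muscle-bone contact forces are zero
there — wrap-generated contact forces appear at more extended or more flexed
postures. Contact forces (the vector sum of the two path-tension directions
at a wrap, pressing the path toward the bone), the active joint torque
$\sum_i r_i F_i$ and the elbow constraint force (the reaction closing the
Newton-Euler force balance of the forearm) are computed from the exact
geometry in post-processing.

## The controller

The desired trajectory is the fifth-order minimum-jerk polynomial between
the start and end angles (default 45° to 75°, onset 0.1 s, duration 0.6 s,
so the final phase starts near $t_2 = 0.7$ s). The total stimulation per
muscle is the clipped sum $u_i = \{u_i^{open} + u_i^{closed}\}_0^1$.

**Open loop.** $u^{open}_i(t)$ is piecewise constant with four phases:
holding level $u^0_i$ before onset; during acceleration $u^{acc}$ for the
agonists and a fixed minimal $u^{min} = 0.005$ for the antagonists; braking
levels $u^{dec}_i$ from $t_1$ to $t_2$; final holding levels $u^{final}_i$.
Branch boundaries are right-continuous. The holding and braking levels are
solved from the equilibrium condition that the net joint torque (including
any bias torque) vanishes at the steady state of the activation dynamics and
the isometric muscle equilibrium, at a configurable co-contraction level:
the solver applies the minimum-norm stimulation correction along the
torque-sensitivity direction and locates the exact torque zero along it.
The braking phase uses a lower co-contraction level than the holding phases
(default `u_des_dec` 0.05 versus 0.1), which is what lets the movement
settle onto the target along the desired path rather than being braked
early; this level is afterwards refined by the gain calibration.

A note on the equilibrium objective: minimizing the plain sum of
stimulations is independent of the desired co-contraction level (the
constraint fixes the weighted difference of flexor and extensor drive, and
the sum is linear), so it cannot express "hold stiffer". The solver
therefore minimizes the deviation from the desired level, which makes the
co-contraction parameter behave as intended: raising it raises every
stimulation while keeping the net torque at zero. The literal
total-stimulation objective remains available (`objective = "total"`).

**Acceleration phase.** $(u^{acc}, t_1)$ are found by seeded Bayesian
optimization (Gaussian-process surrogate, squared-exponential kernel on the
normalized box, expected-improvement acquisition; default budget 60
evaluations with a 10-point Latin-hypercube start), minimizing the mean
squared pointwise difference between the simulated and the desired angle
trajectory. Candidates whose simulation fails — leaves the anatomical range
or stalls the integrator — are rejected and penalized. $t_1$ is searched up
to 75% of the onset-to-$t_2$ interval so that a braking phase structurally
exists. The search is fully reproducible from its seed.

**Closed loop.** The feedback law is delayed PD on the muscle-fiber state,

$$ u^{closed}_i(t) = \frac{k_p}{l_{CE,opt}}\big(l^i_{CE}(t-\delta) - \lambda^i(t-\delta)\big)
 + \frac{k_d}{l_{CE,opt}}\big(\dot l^i_{CE}(t-\delta) - \dot\lambda^i(t-\delta)\big), $$

where $(\lambda, \dot\lambda)$ are the fiber lengths and velocities recorded
during the unperturbed open-loop movement, and $\delta$ is 25 ms
(short-latency, spinal stretch reflex) or 50 ms (long-latency). In an
unperturbed trial the error — and with it the closed-loop signal — vanishes.

**Gain calibration.** $(k_p, k_d, u^{des,dec})$ are calibrated with a
Hooke-Jeeves pattern search that minimizes the sum, over the four static
perturbation types, of squared early-velocity and dysmetria differences
(perturbed minus unperturbed), each normalized by the largest standard
deviation of that measure across perturbation types. The experimental means
and standard deviations this cost needs are not part of the package's data;
a synthetic reference table
(`inst/extdata/synthetic_perturbation_reference.csv`, clearly labeled
synthetic) encodes the qualitative response pattern reported for this class
of exoskeleton experiments — added inertia slows the early movement and
makes it overshoot, added damping slows it and makes it undershoot, the
reductions mirrored — with plausible magnitudes (10-15°/s, 1-2°). A user
with real summary statistics can supply them in the same format. During the
search the acceleration-phase parameters stay fixed; if the braking
co-contraction moved, the acceleration phase is re-optimized once at the
end. Gain search bounds are $k_p \in [0,2]$, $k_d \in [0,0.1]$ s: a
stability scan of this plant shows the delayed spindle loop develops a
growing high-frequency mode for $k_p \gtrsim 2$ at 50 ms delay, and the
calibration is restricted to the stable region.

## Delay handling and numerics

The delayed feedback makes the closed-loop system a delay differential
equation. It is integrated by the method of steps: `deSolve::lsoda`
(relative tolerance $10^{-5}$, the variable-step stiff-capable solver)
proceeds in segments no longer than the delay, with breakpoints also at the
stimulation-pattern switching times and at impulse onset/offset, and `tcrit`
pinned to each segment end so the solver never evaluates beyond the
available history. Lagged fiber states are read from interpolants of the
accumulated dense output: cubic Hermite with the *exact* nodal velocities
for the length channel, and piecewise-linear for the velocity channel. Both
interpolants are local — each interval depends only on its own nodes — so a
growing history agrees exactly with the full recording on their common span.
Together with recording the reference on the raw solver time base (which
contains the same segment boundaries a replay will use), this makes the
unperturbed closed-loop replay *bit-identical* to the recording and the
closed-loop signal exactly zero, rather than zero up to solver noise. That
matters because the delay loop amplifies any numerical seed over the trial;
with interpolation-level mismatches the "vanishing" feedback signal would
grow to order $10^{-4}$ by the end of a trial. The linear interpolation of
the velocity channel is the one place the implementation drops below
third-order interpolation; its error (about $10^{-6}$ m/s at 1 kHz sampling)
is far below the solver tolerance, and the length channel retains the
higher-order local interpolant.

Trial horizon is 1.0 s with 1 kHz dense output. Simulation problem sizes
are desk-scale throughout: a single trial integrates in a fraction of a
second, a full calibration in tens of seconds, and the complete pipeline
(both reflex latencies, all protocols) in minutes. The test suite and the acceptance
script both use the default optimizer budgets (60 trajectory evaluations
for the acceleration phase, 24 cost evaluations for the gains).

## The simulation experiments

`run_static_protocol()` runs the unperturbed reference plus the four
whole-trial plant modifications ($\Delta I = +0.039 / -0.032$ kg·m²,
$\Delta d = +0.30 / -0.31$ N·m·s/rad) in the horizontal plane with an
identical controller — nothing is re-tuned per perturbation.
`run_dynamic_protocol()` adds the constant $-1.5$ N·m bias and fires
$\pm 5$ N·m, 37.5 ms impulses during flexion and extension movements; the
controller is re-calibrated once for each biased movement context (the
equilibria and the acceleration phase; the feedback gains and co-contraction
levels transfer unchanged). Evaluation statistics:

* **early velocity** — the joint velocity 155 ms after the speed first
  exceeds 10°/s;
* **dysmetria** — the difference between the position at trial end (1 s) and
  at the first correction, where the first correction is the first time
  *after the end of the primary deceleration* at which the speed drops below
  2°/s or the acceleration magnitude below 2°/s². Restricting the search to
  after peak deceleration avoids the trivial acceleration zero-crossings at
  movement onset and at peak velocity, which would otherwise satisfy the
  letter of the definition at times that are clearly not "corrections". With
  this convention an overshoot yields negative dysmetria. If no first
  correction occurs before 1 s the metric is 0 with a warning;
* **velocity quotient** — velocity at impulse onset over velocity $\Delta t$
  later ($\Delta t$ = the impulse duration, and 100 ms);
* **feedback contribution** — the share of the closed-loop signal in the
  total neural drive, $\max_t \sum_i |u^{closed}_i| / \sum_i u_i$. The
  per-muscle instantaneous ratio is also available but is documented as
  ill-behaved: whenever an antagonist's total stimulation clips to (near)
  zero while its feedback component does not, the per-channel ratio diverges
  regardless of how weak the feedback is, so it cannot characterize the
  feedback's overall share.

The torque-driven comparison model drives the same rigid plant with the net
joint torque recorded from the unperturbed musculoskeletal movement, plus —
optionally — delayed PD feedback on the joint-angle error against the
desired trajectory (100 ms delay, a long-latency joint-level reflex; default
gains 5 N·m/rad and 1.2 N·m·s/rad, chosen so the controller reaches the
target with a visible terminal oscillation — larger gains are unstable under
the 100 ms delay with this plant). Its open-loop impulse response is purely
rigid-body ($\Delta\omega = \tau\,\Delta t/I$ to within integration
tolerance), which makes it the baseline against which the muscles'
zero-time-delay visco-elastic reaction (the preflex) is quantified.

## Design choices made during model construction

The segment, muscle and routing constants are a generic default set, not a
subject-specific one, and three of them were deliberately set by
requirements of the studied behavior rather than taken from first guesses:

* **Muscle sizes** ($F_{max}$ = 400/465/300/365 N). With muscles several
  times stronger, this 30°-in-0.6 s task runs at ~5% activation, where the
  activation-scaled Hill constants pin the fibers near their (activation-
  dependent) maximal shortening velocity. The muscles then act as heavy
  dampers: the velocity profile flattens instead of being bell-shaped and
  inertia perturbations are almost perfectly compensated, contrary to what
  the perturbation experiments show. The default sizes put the task at
  15-30% activation — typical surface-EMG burst levels for moderate-speed
  point-to-point movements.
* **Tendon stiffness** (2% toe strain). With a compliant 4%-strain toe the
  tendon absorbs nearly the whole fiber-length excursion of a 37.5 ms
  impulse at task-level forces, suppressing the immediate muscular force
  response; the measured preflex then attenuates almost nothing. The stiff
  characteristic is at the stiff end of published tendon-aponeurosis data.
* **PEE slack at** $l_{CE,opt}$. An earlier slack at $0.95\,l_{CE,opt}$
  generated a parasitic passive flexion bias of several N·m at the start
  posture, which the trajectory optimizer exploited by dropping all
  stimulation and letting the passive field carry the movement — good
  tracking, no triphasic burst, no perturbation phenomenology.

SEE rest lengths are derived at a reference posture (60°, the movement
mid-point) so each fiber sits at its optimal length with the tendon just
slack there.

## What the simulations do and do not show

All quantitative findings the package reports are emergent from this one
parameter set: the qualitative static-perturbation pattern (slower/overshoot
under added inertia, slower/undershoot under added damping, mirrored for the
reductions, and the torque model undershooting where the muscle model
overshoots), the approximate doubling/halving of velocity across the
impulse window, the preflex attenuation relative to the rigid torque model,
and the smallness of the feedback share of the neural drive. Because the
experimental summary statistics behind the gain-calibration cost are a
synthetic stand-in, the *absolute* cost values of the calibration are not
comparable to values computed against real data, and nothing in the package
claims quantitative agreement with any particular experimental dataset.
Passing tests demonstrate internal consistency and the qualitative
phenomenology under the documented study conditions; they do not validate
the parameter set against a specific subject or robot.

Known limitations, beyond those inherited from the modeling class: no
eccentric history effects or short-range stiffness; no Golgi-tendon-organ
pathway and no alpha-gamma co-activation (the spindle model feeds back ideal
delayed fiber length and velocity, and reacts to shortening as well as
stretch); planar routing only; one degree of freedom; no trial-to-trial
learning or adaptation. The "kg·m·s²" unit sometimes printed for robotic
inertia perturbations is read as kg·m².

## Reproducing the study

```{r}
library(nmsarm)

model <- build_model()
calib <- calibrate_controller(model, delay = 0.05, seed = 1)
static <- run_static_protocol(model, calib)
static$metrics

report <- reproduce_all(seed = 1, delay = 0.05, out_dir = "out")
report$checklist
```

`scripts/acceptance.R` runs the full pipeline for both reflex latencies and
writes the maximal feedback shares to JSON; see the README.
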