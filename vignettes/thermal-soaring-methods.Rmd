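---
title: "Methods: thermal soaring simulation, learning and track analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal soaring simulation, learning and track analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermalsoar)
```

## The problem

Soaring birds and gliders gain altitude by circling inside thermals —
columns of rising air that drift with the horizontal wind. Staying inside a
drifting thermal while keeping the aircraft stable is a non-trivial control
problem: the updraft is invisible, the core moves downwind, and tight
circling costs sink rate. `thermalsoar` implements a complete desk-scale
laboratory for this problem: a point-mass glider simulator in a drifting
thermal, an episodic reinforcement-learning (RL) environment with shaped
rewards, a curriculum-trained actor–critic agent, and the analysis toolkit
(efficiency metric, climb-rate bounds, kinematic estimators, activation
clustering) used to interrogate both simulated agents and bird-style 1 Hz
GPS tracks.

## Atmospheric model

The updraft is an axisymmetric chimney,

$$w(r, z) = w_{core}(z)\, e^{-(r/R(z))^2}\!\left[1 - (r/R(z))^2\right],$$

with vertical profiles

$$w_{core}(z) = w^* (z/z^*)^{1/3}(1 - 1.1\, z/z^*), \qquad
  R(z) = 0.08\, (z/z^*)^{1/3}(1 - z/(4 z^*))\, z^*.$$

`w_star` ($w^*$, m/s) sets the updraft amplitude and `z_star` ($z^*$, m)
the characteristic thermal altitude; the nominal configuration is
$w^* = 5$, $z^* = 2000$, for which the core peaks near 2.3 m/s around the
500 m start altitude and the thermal radius there is ~94 m. The updraft
core is surrounded by a ring of sinking air beyond $r = R(z)$, with the
strongest downdraft at $r = \sqrt{2} R$. The horizontal wind is uniform,
speed $u$ along $+x$, with no vertical shear; the thermal center starts at
the origin and drifts passively at $u$, keeping a vertical centerline
(`wind_vector()`). Above $z = z^*/1.1$ the literal profile turns weakly
negative; episodes never approach that altitude, and the formula is applied
as printed. Optional gusts resample the effective wind from
$\mathcal N(u, \sigma_{gust})$ every 20 s (truncated at zero, seeded); the
thermal keeps drifting at the mean wind, since the core advects with the
mean flow rather than with instantaneous gusts.

## Glider model

The glider is a point mass with state $(x, y, z, V, \gamma, \chi)$: position,
air-relative speed, glide angle and side (heading) angle. Quasi-steady
aerodynamics close the model: a linear lift curve
$C_L = C_{L0} + C_{L\alpha}\,\alpha$, a quadratic drag polar
$C_D = C_{D0} + k\, C_L^2$ and a linear side-force law in the sideslip
$\beta$ (carried in the model, held at zero by the nominal controller).
Speed and flight-path angles evolve under lift, drag, side force and
gravity in the frame of the moving air; the position integrates the ground
velocity, i.e. the air-relative velocity plus the local air motion. In
still air the system is exactly the classical point-mass glider. This
coupling is what makes thermalling work at all: a steady circle has a
negative air-relative sink rate, and the ground-frame climb is that sink
plus the updraft at the circling radius. Formulations that keep the
velocity state in the ground frame and only rescale the force magnitudes
admit no climbing steady state and were rejected on those grounds.

Controls are the bank angle $\sigma \in [-50°, 50°]$ and angle-of-attack
$\alpha \in [-30°, 30°]$, commanded in steps of at most $\pm 15°$ and
$\pm 10°$ per second.

### Calibration of the aerodynamic coefficients

The packaged `"vulture"` preset uses $m = 7.75$ kg, $S = 0.87$ m²,
$\rho = 1.225$ kg/m³ (standard sea level) and $g = 9.81$ m/s². The four
polar coefficients are not independently measurable from the package's two
behavioural anchors, so two were fixed at conventional values
($C_{L0} = 0.30$, $k = 0.05$) and the remaining two calibrated so that:

1. the still-air straight glide at $(\sigma, \alpha) = (0°, 6°)$ settles at
   $v_z = -0.75$ m/s (the baseline sink), and
2. the best constant-control steady circle inside the nominal thermal at
   $z = 500$ m climbs at $+0.72$ m/s (the optimal bound).

The calibrated values are $C_{L\alpha} = 0.02347539$ /deg and
$C_{D0} = 0.00868575$; both anchors reproduce to numerical precision
(`baseline_climb_rate()`, `optimal_climb_rate()`). The resulting polar has
a best glide ratio of ~24 at $\alpha = 6°$ and a baseline glide speed of
~18 m/s. The linear lift curve has no stall; the steady-circle solver
therefore restricts $\alpha$ to $[-5°, 15°]$, the usable pre-stall
incidence range, and the optimum sits at that upper incidence limit —
slow, tight circling is aerodynamically favoured right up to the stall a
real wing would impose.

### Numerics

Integration is classical fourth-order Runge–Kutta at a fixed 0.05 s step,
twenty sub-steps per 1 s control interval. Halving the step moves a 200 s
endpoint by well under 0.1 m (tested), and a trajectory started on the
algebraic steady circle stays on it. Instability is declared when the
airspeed falls below $V_{min} = 2$ m/s, when $|\gamma|$ reaches 90° (the
coordinate singularity that stands in for a pitch spin in a point-mass
model), or when an externally supplied pitch history accumulates 360° of
same-direction rotation. A crash is $z \le 0$.

## The RL environment

Episodes last 200 s with a 1 s control interval. The observation is the
6-vector $\{V, v_z, \sigma, \alpha, \theta, u\}$ — ground speed, climb
rate, bank, angle-of-attack, angle from the wind, and wind speed — plus a
memory buffer of the 8 previous control steps (front-padded at episode
start), every entry affinely normalized to $[-1, 1]$ and clipped. The
normalization ranges ($V \in [0, 30]$ m/s, $v_z \in [-5, 5]$ m/s,
$\sigma \in [-50°, 50°]$, $\alpha \in [-30°, 30°]$,
$\theta \in [-180°, 180°]$, $u \in [0, 10]$ m/s) cover the envelope the
glider actually visits with margin; they are package choices, documented
here because nothing in the flight physics pins them exactly.

$\theta$ is the signed angle between the planar velocity and the upwind
direction: 0 is headwind, ±180° tailwind, and the sign is mirrored by the
sense of rotation (estimated from the mean heading rate over the last 5 s)
so that $\theta$ increases through the headwind→tailwind half-circle for
either circling direction. With zero horizontal speed the previous value is
held.

The per-step reward is the climb $v_z$ (implemented as the altitude gained
over the interval, so episode sums telescope exactly) plus a centering
penalty $P_{center} = -d/50$ with $d$ the horizontal distance to the
drifted thermal center at the end of the step. Going unstable ends the
episode with $P_{stab} = -1$ per remaining second; hitting the ground costs
$-1000$. The reward variants `"vz"`, `"vz+stab"`, `"vz+center"` expose the
reward-shaping ablations.

Episodes start at $z = 500$ m, $V = 15$ m/s, $\gamma = -5°$, uniformly
random heading, and a uniformly random position on an annulus 80–150 m
from the thermal center — close to, but outside, the positive-updraft
core, which produces a short search phase before thermalling can begin.
The annulus bounds are a package choice consistent with that behaviour.
Optional sensor noise is Gaussian on the raw physical values before
normalization (physical sensor noise rather than post-normalization
noise), with per-variable levels expressed relative to typical trajectory
standard deviations ($V$: 2.3 m/s, $v_z$: 2.6 m/s, $\sigma$: 11.9°,
$\alpha$: 5.9°, $\theta$: 116.4°; $u$ in absolute m/s).

## Learning

The learner is a deterministic-policy-gradient actor–critic (DDPG): actor
and critic with two fully connected hidden layers of 200 rectified units,
tanh-bounded actions scaled to the per-step limits, replay buffer (10^5
transitions), target networks with Polyak averaging ($\tau = 0.005$),
discount 0.99, Adam at $10^{-3}$, Gaussian exploration noise (sd 0.1 in
normalized units) and rewards scaled by 0.01 inside the critic update.
These are conventional values for this family of learners, not tuned
search results. No RL library is involved: the networks, backpropagation
and optimizer are implemented in plain matrix algebra
(`ddpg_agent()`), which keeps the learner fully inspectable — the same
forward pass that drives the policy is replayed by
`extract_activations()`.

Curriculum training (`curriculum_train()`) widens the wind range over
stages — nominally 0–2, 0–4, 0–6 m/s — carrying weights across stages and
checkpointing by cumulative simulated time. The full-scale protocol uses
3–5 × 10^6 simulated seconds per stage; the package defaults to 2 × 10^5 s
per stage (`scripts/curriculum_full.R`, hours on one CPU), and the test
suite exercises the pipeline at a few hundred simulated seconds per stage,
which verifies the machinery but is far too little training to produce a
soaring policy. Training logs record per-episode return, stable-flight
fraction, time-in-thermal fraction and mean climb, so the learning
bottleneck ordering (stability before centering; see
`scripts/bottleneck_report.R`) can be inspected at any budget.

## Efficiency metric and its bounds

Soaring performance is scored by

$$\eta = \frac{v_z^{agent} - v_z^{baseline}}{v_z^{optimal} - v_z^{baseline}},$$

the fraction of the exploitable updraft actually used. The baseline is the
best still-air straight glide ($-0.75$ m/s); the upper bound is the best
constant-control steady circle in the thermal. The steady state under
constant $(\sigma, \alpha)$ has a closed algebraic form (`steady_turn()`):
$\tan\gamma = -C_D / (C_L \cos\sigma)$, equilibrium speed from the vertical
force balance, radius $V^2 \cos\gamma / (g \tan\sigma)$; the solver adds
the updraft at that radius and maximizes over a $(\sigma, \alpha)$ grid
with local polish (`optimal_climb_rate()`). The bound is evaluated at the
500 m start altitude by default. $\eta$ can leave $[0, 1]$: the bound
assumes a fixed circle in the thermal frame, and nothing constrains an
agent to it. `fit_thermal_params()` inverts the solver to find the
$(w^*, z^*)$ whose optimal climb and radius match observed targets — the
route by which observed bird climb statistics select study thermals.

## Kinematic estimators

All estimators consume plain 1 Hz $(t, x, y, z)$ tables and therefore apply
equally to simulator output and bird-style GPS tracks.

* **Bank angle** (`estimate_bank()`): in a banked turn,
  $\tan\sigma \approx a_r / g$ with drag and vertical acceleration
  neglected. $a_r$ is the component of the second-difference acceleration
  perpendicular to the central-difference velocity. At 1 Hz sampling the
  second difference underestimates the centripetal acceleration of a circle
  by a factor $\mathrm{sinc}^2(\omega/2)$ (~2–4% at typical thermalling
  turn rates), a bias that stays well inside the 7% validation envelope of
  `validate_bank_estimator()`.
* **Wind** (`estimate_wind()`): the mean planar velocity over an entire
  thermalling trajectory, trimmed to a whole number of circles (cumulative
  heading a multiple of 360°, end interpolated) so that the circling
  component cancels exactly; under two full turns triggers a bias warning.
* **Thermalling diameter** (`thermalling_diameter()`): crossings of
  $\theta$ through 0 (against wind, type B) and ±180° (with wind, type A)
  are interpolated to sub-second precision, time-sorted, and consecutive
  ABA / BAB triples each yield one local diameter: the altitude from the
  middle vertex. The altitude is computed as the apex-to-base-segment
  distance, which equals the triangle altitude whenever the foot lies
  inside the base and remains well-conditioned in the small-drift limit
  where the base vertices nearly coincide (tending to the diameter, as it
  should).
* **Segment selection** (`select_thermalling_segments()`): maximal spans
  with a consistent smoothed heading-rate sign, at most 10% retrograde
  steps, at least two net turns and at least 100 s duration. Field datasets
  rarely come with a published definition of "consistent thermalling"; this
  criterion is a package convention and is labelled as such.

## Activation clustering

`extract_activations()` replays logged observations through the actor and
concatenates both hidden layers (400 non-negative values per step).
`cluster_activations()` runs k-means (10 restarts, fixed seed) for each
candidate $k$ (default 1–10), repairs any non-monotone SSE by warm-starting
from the previous solution, and picks $k$ at the knee of the SSE curve —
the point of maximum distance to the chord joining the curve's endpoints,
a parameter-free variant of the knee/elbow rule. The actor (not the
critic) is inspected, as the network that actually produces behaviour;
activations enter unstandardized by default (the rectified values are
already commensurate), with a standardized variant behind a flag.
`cluster_theta_distribution()` histograms each cluster over 24 $\theta$
bins and scores phase association as the mean, over clusters, of the mass
inside the cluster's best contiguous circular arc of $\lceil 24/k \rceil$
bins: phase-locked labelings score near 1, $\theta$-independent ones near
$1/k \cdot \lceil 24/k \rceil / 24 \cdot k$ (≈ the arc fraction).

## What the synthetic fixtures do and do not show

`scripted_circler()` flies constant-control circles and trochoids through
the same dynamics as the learning agent, with algebraic ground truth
(bank, wind, steady radius) attached. These fixtures validate the
estimators against known truth — which real GPS tracks never provide —
but they are cleaner than bird data in specific ways: no GPS noise, no
thermal leaning, no within-thermal turbulence, no behavioural variation in
bank, and perfectly uniform wind. Estimator accuracy measured on them
(e.g. the ~1% mean bank error) is therefore an upper bound on real-data
performance; the validation bound of 7% is the meaningful envelope. The
same holds for the RL results: the environment contains exactly one
thermal with a known profile, so learned policies demonstrate the
tractability of the control problem, not a claim about real atmospheric
boundary layers.

## Problem sizes

The shipped defaults keep every routine desk-scale: estimator validation
uses 20 × 200 s fixtures (~20 s of computation), evaluation runs are 200 s
episodes at ~60× real time, and the test suite trains only smoke-scale
agents (hundreds of simulated seconds). The reduced curriculum
(3 × 2 × 10^5 s) and the reward-ablation study are provided as scripts and
take hours on a single core; the full-scale budgets remain available
through the training configuration.

## Known limitations

* The aerodynamic closure is calibrated, not measured: two coefficients
  are conventions, two are fitted to the two behavioural anchors, and the
  lift curve has no stall (the solver's incidence cap stands in for it).
* The thermal model is a single drifting chimney without centerline
  leaning, multiple cores, or turbulence beyond optional piecewise-constant
  gusts.
* The point-mass model cannot represent attitude dynamics, so "spinning in
  pitch" is detected via its coordinate singularity rather than simulated.
* Desk-scale training budgets do not produce soaring policies; they verify
  the learning machinery. Producing an agent with positive efficiency
  across winds requires the script-scale budgets.
* The thermalling-segment criterion is a stand-in for an undefined
  field-data convention.
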