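---
title: "Two-system motor learning in rotated visual environments: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-system motor learning in rotated visual environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotadapt)
```

## The scientific question

When people practice reaching movements under rotated visual feedback, they
adapt — and when the rotation is removed they transiently err in the opposite
direction (an *aftereffect*). Aftereffects are the standard behavioural
signature of an internal model having changed. The question this package
addresses computationally is *which* internal structure changed: the skill
itself (the planned movement toward a target) or a separate representation of
the visuomotor environment.

`rotadapt` simulates three candidate architectures through the standard
baseline / interference / re-adaptation block design and applies the same
aftereffect statistic to simulated, synthetic and recorded sessions:

* **Model A** — one basis-function network shared across all targets and
  environments. Every error, whatever its source, reshapes the same weights.
* **Model B** — one network per reaching target (a "motor program" store).
  Errors only reshape the network of the target being practiced.
* **Model C** — the two-system model: one task network per target trained on
  *performance error* (desired minus sensed position), plus a single shared
  2×2 forward model of the environment trained on *sensory prediction error*
  (sensed minus internally predicted position), inverted on-line to remap
  motor commands.

The three architectures make different predictions about when aftereffects
occur. A change of environment (experiments 1 and 3) and a change of task
(experiment 2) dissociate them: only the two-system model predicts
aftereffects exactly when the environment changes — whether or not the
required hand movement changes — and never for a pure task change.

## Model components

**Geometry and conventions.** Angles are in degrees, measured
counterclockwise from straight up (0° = straight up), in a y-up screen frame.
The plant is the 2×2 rotation
\[
P(\theta) = \begin{pmatrix} \cos\theta & \sin\theta \\ -\sin\theta & \cos\theta \end{pmatrix},
\]
applied to motor commands (pen positions); positive \(\theta\) rotates the
display clockwise, so a command heading at angle \(a\) is displayed at
\(a - \theta\) and the hand must aim at \(T + \theta\) to hit an on-screen
target \(T\). The baseline environment of every experiment is
\(\theta = +10\); interference rotations are relative to it. Whether screen
y really grows upward on the apparatus cannot be decided from the protocol;
the convention is internally consistent, and only the *sign* of reported
deviations (never a magnitude or a significance decision) depends on it.

**Desired trajectory.** A straight path to the target with a bell-shaped
speed profile: a Gaussian in normalized time (\(\sigma = 0.15\), centred at
0.5), truncated to \([0,1]\), lowered by its boundary value so speed is zero
at start and end, and rescaled so the path ends exactly on the target. The
profile width is not identified by the protocol; 0.15 gives a single smooth
peak with negligible boundary speed, matching how point-to-point reaches
look. Movements last 1 s sampled at 50 Hz (51 samples including the origin).

**Task network.** Planned positions are weighted monomials of normalized
time, \(x_p(t) = \sum_{i=0}^{n} W_{xi}\, t^i\) (and likewise for y), with
degree \(n = 5\) — the lowest degree whose least-squares fit of the
bell-profile path stays under 2% of the movement amplitude. Weights learn by
the Widrow–Hoff (LMS) rule once per trial from the whole movement's
performance error: \(\Delta W_{xi} = \lambda \sum_j x_e(t_j)\, t_j^i\).
The degree-0 weight never influences behaviour (only velocity differences
enter the controller), but it is part of the printed rule and is kept.

**Environment adapter (model C only).** A general 2×2 forward model
\(\hat P\), updated by the rank-1 LMS rule
\(\Delta \hat P = \alpha_e\, e_p\, [x'_c\ y'_c]^T\) and inverted to remap
commands, \([x'_c\ y'_c] = \hat P^{-1} [x_c\ y_c]\). Per-instant updates are
accumulated over the movement and applied once per trial — the same schedule
as the task network — with the per-sample rate scaled by `1/n_samples` so the
cadence choice does not change the effective learning rate (a per-sample
cadence is selectable via `motor_control(adapter_cadence = "sample")`).

**Online feedback controller.** Command velocity is planned velocity plus
delayed proportional feedback of the on-screen error,
\(v'(t) = v(t) + \gamma\, e(t - t_d)\), integrated into the command position.
The delay is 100 ms (5 samples at 50 Hz), the order of magnitude of human
visual reaction time; samples earlier than the delay use zero feedback. The
feedback against the *desired trajectory at the same time index* produces the
characteristic terminal "hook" in perturbed reaches.

**Outcome measure.** The initial movement direction: the angle from the start
to the point of maximum speed (central finite differences, earliest sample on
ties), read from the sensed (on-screen) trajectory. The aftereffect statistic
is \(Z = (x_{c1} - \mu)/\sigma\), where \(x_{c1}\) is the first
re-adaptation-block trial and \(\mu, \sigma\) are the sample mean and (n−1)
standard deviation of the last ten baseline trials; \(|Z| > 1.96\) flags a
significant aftereffect at \(\alpha = 0.05\). A zero-variance baseline is
reported as degenerate rather than divided by.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `gamma` | 0.04 | per sample | largest gain that keeps corrections overdamped under launch errors up to 20° while pulling endpoints onto the target; larger values ring visibly |
| `delay_samples` | 5 | samples | 100 ms visual feedback delay at 50 Hz |
| `lambda` (A, B) | 0.03 | per trial | removes ≥ 80% of the initial-direction error induced by a 20° rotation within 20 trials — the human adaptation speed — while staying clearly inside the stability region (the closed loop destabilizes near 0.06–0.08) |
| `lambda` (C) | 0.002 | per trial | model C's task networks are the *slow* system; environment changes are absorbed by the adapter, and a slow task rate is what keeps task memory intact across environment changes |
| `alpha_e` | 2 | per trial (scaled by 1/51 per sample) | the *fast* system: re-adapts a 20° environment change within a handful of trials while leaving a measurable first-trial aftereffect |
| `degree` | 5 | — | lowest monomial degree fitting the bell path to < 2% |
| `n_samples` | 51 | — | 1-s movement at 50 Hz |
| `sigma_bell` | 0.15 | normalized time | single smooth speed peak, zero boundary speed |
| `noise_sd` | 1.5 | degrees | measurement noise on recorded initial directions; gives baseline variability comparable to the per-participant baseline SDs implied by the human z-tables |

The learning rates were tuned only against those stated criteria, with the
measurement layer switched off; they were not adjusted to any statistical
outcome downstream.

## Numerical and design choices

* **Pretraining.** Each architecture "practices" several hundred reaches per
  target (0/20/40/60°) in the veridical environment before any experiment.
  Task networks are warm-started at the closed-form least-squares fit of the
  desired path and then run the practice trials: participants are assumed to
  already know the optimal straight reach, and raw-monomial LMS from zero
  weights cannot reach that solution in realistic trial counts (the monomial
  design matrix has Hilbert-matrix conditioning, ~1e7 at degree 5, so its
  slow modes converge many orders of magnitude more slowly than its fast
  ones). With the warm start, pretraining is maintenance: weights settle at
  the closed-loop equilibrium and per-trial drift is negligible.
  `n_pretrain = 0` gives a genuinely naive zero-weight learner.
* **Sequential batteries.** Experiments run back to back on one learner with
  no reset, so the +10° baseline learned in experiment 1 carries into
  experiments 2 and 3 (no learning curve there), as in a single session.
* **Unseen targets** (architectures B/C) spawn a fresh network initialized by
  the least-squares fit of the veridical desired path — equivalent to having
  been pretrained.
* **Inversion guard.** \(\hat P\) stays numerically a near-rotation in
  practice; if its condition number ever exceeds 1e6 the inverse is
  Tikhonov-regularized (ridge \(10^{-8}|\mathrm{tr}\,\hat P|\)), and an
  exactly singular model signals a typed error that the simulator answers
  with an identity remap for that trial.
* **Noise model.** The learning loop is deterministic; zero-mean Gaussian
  noise (default SD 1.5°) is added only to the *recorded* initial direction.
  This separates the deterministic model from the statistical harness: fixed
  seeds give bit-identical batteries, and significance statistics can be
  studied by resampling the measurement layer alone.
* **Ties and ends.** Peak-speed ties resolve to the earliest sample;
  one-sided differences are used for the speed at the trajectory ends.

## What the simulations show

Running the battery noiselessly reproduces the predicted sign pattern of
aftereffects per architecture — the package's central result:

```{r pattern, eval = FALSE}
for (kind in c("A", "B", "C")) {
  bat <- run_battery(motor_model(kind), 1:3, noise_sd = 0)
  dev <- vapply(bat$sessions, function(s)
    s$trials$initial_direction_deg[41] - s$trials$target_deg[41], 0)
  cat(kind, sprintf("% .1f", dev), "\n")
}
#> A -16.8  13.6 -1.5
#> B -15.7 -0.7 -0.2
#> C -18.1  0.3 -16.0
```

Model A shows aftereffects in experiments 1 *and* 2 (a shared network makes
target practice interfere); model B in experiment 1 only (nothing
generalizes); model C in experiments 1 and 3 but not 2 — aftereffects if and
only if the environment changed, the two-system signature. In model C the
per-target weights change by less than 1% in norm across experiment 3 while
the plant model swings between rotations: the trajectory generator does not
change, the environment model does.

Two quantitative caveats surfaced by the simulations are worth knowing:

* **Directional excitation.** All commands in a block lie along (a sweep of)
  one ray, so the rank-1 adapter updates constrain \(\hat P\) only on the
  visited directions. \(\hat P\) matches the true rotation to high accuracy
  where the system operates, but never globally under this protocol; full
  2×2 recovery requires full 2-D excitation (shown with random commands in
  the tests). A small cross-target "bleed" of updates is the flip side and
  produces sub-degree deviations at block boundaries.
* **Re-adaptation floor.** Architectures that must re-learn the experiment-1
  rotation with task LMS (A and B) end the re-adaptation block ~2–4° short
  of the target at the fastest stable learning rate; the adapter-driven
  model C returns to well under 1°.

## The synthetic session generator

`synth_session()` is a deliberately phenomenological stand-in for human
participants, *not* the mechanistic simulator — so tests of the analysis
pipeline cannot inherit simulator bugs. Per block it draws
\(\text{target} + J\,(1-r)^{t-1} + \varepsilon_t\): the block-B jump is the
on-screen consequence of the environment change (\(\theta_A - \theta_B\);
zero in experiment 2), the block-C jump is \(-f\) times the amount adapted in
block B, adaptation removes a fraction \(r\) (default 0.25) of the remaining
error per trial, and \(\varepsilon_t\) is Gaussian (default SD 3°). Defaults
were chosen to resemble the group error-decay curves of the human data:
interference errors largely gone within a handful of trials, aftereffects
slightly smaller than the injected rotation (`aftereffect_frac = 0.9`).

It emulates per-trial initial directions only — no within-trial
trajectories, no curvature, no reaction times, no participant
heterogeneity in adaptation rate — so power calculations made with it
speak to the *statistic*, not to every property of real kinematics.
Sessions read and write the deposited-dataset CSV layout (one initial-angle
column per participant plus a `target` column, 60 rows = 3 blocks × 20
trials), and the analysis functions treat simulated, synthetic and
CSV-loaded sessions through one code path.

A statistical note the generator makes visible: the aftereffect test plugs a
10-trial sample SD into a z-criterion, so its true null exceedance rate is
\(P(|\sqrt{1.1}\,t_9| > 1.96) \approx 0.094\), about twice the nominal
\(\alpha = 0.05\) — consistent with the nonzero significance counts human
cohorts show in the no-aftereffect condition. Detection probability crosses
50% near \(\Delta = 1.96\,\sigma\sqrt{1 + 1/10}\), which the tests verify by
Monte Carlo against the noncentral-t closed form.

## Problem sizes

The shipped tests pretrain with 100–300 trials per target, run full 60-trial
experiments and 180-trial batteries, use 50 noise seeds for the sign-pattern
check, 250–400 synthetic participants for power and calibration checks, and
500 random commands for adapter parameter recovery. The whole suite runs in
about two minutes on one CPU.

## Limitations

* Arm dynamics are not modeled: commands are desired pen positions, and the
  plant is purely the visual rotation.
* Tasks are a discrete store of per-target networks; a continuum of targets
  would need interpolating representations.
* Environment switching is error-driven only — no cue-triggered instant
  switching after extensive practice.
* Errors live in the visual domain; proprioceptive channels are absent.
* The 90° variant is provided for exploration (targets 90/180/270°, 90°
  rotation between environments), but large rotations push the shared- and
  per-target-network architectures toward their closed-loop stability limits,
  and humans are known to behave qualitatively differently beyond ~45°.
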