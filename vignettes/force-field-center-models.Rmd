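---
title: "Models, simulation and fitting choices in fieldcenter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulation and fitting choices in fieldcenter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldcenter)
library(dplyr)
```

`fieldcenter` analyzes a deceptively simple haptic task: a device
renders a weak linear spring field along a 20 cm line and the
participant must place the handle where the force is zero. Because
forces below the detection threshold are imperceptible, a band around
the true center gives no usable signal, and how people bridge that band
is diagnostic of whether they integrate force and position information.
This vignette is the package's account of the two candidate models, the
synthetic experiments used to validate the chain, and the numerical and
design choices behind the implementation.

## The two models

Both models sit on a Stevens power law for perceived force,
$\tilde F = \alpha (F - F_{th})^{\beta}$ for $F > F_{th}$ and zero
below, with the exponent defaulting to $\beta = 0.8$, a value typical
of force-magnitude perception on haptic devices. The scale $\alpha$
cancels out of every prediction; it is retained in `perceived_force()`
only so the transducer is complete. Model math runs in a frame whose
origin is the true field center, positive rightward; everything
internal is SI (N, m, N/m), with centimeters confined to the
human-facing report files.

**Bisection.** The observer finds the two positions where the force
fades into the threshold, at $-F_{th}/K_{left}$ and $+F_{th}/K_{right}$,
and reports their weighted midpoint. The weight is fixed at $w = 1/2$
throughout (the device is assumed at the body midline; the parameter is
stored for generality but never fitted). Bias and variability follow as

$$\mu_x = \tfrac12\left(\frac{-F_{th}}{K_{left}} + \frac{F_{th}}{K_{right}}\right),
\qquad
\sigma_x^2 = \tfrac14\left(\frac{\sigma_F^2}{K_{left}^2} +
\frac{\sigma_F^2}{K_{right}^2} + 2\sigma_P^2\right),$$

with $\sigma_F$ the SD of the threshold and $\sigma_P$ the SD of sensed
hand position. When visual feedback of hand position is manipulated,
$\sigma_P$ splits into a feedback-present and a feedback-absent value
while $F_{th}$ and $\sigma_F$ are shared — feedback can only inform the
position sense. A unilateral field keeps one term:
$\mu_x = F_{th}/K$ toward the spring, $\sigma_x^2 = \sigma_F^2/K^2 +
\sigma_P^2$.

**Stiffness extrapolation.** The observer instead estimates the local
stiffness as the slope of the psychophysical function and extrapolates
the perceived force to zero. With the power-law offset placed at the
threshold position $x_0$, stiffness and scale cancel and the
extrapolated edge from a probe at $x$ is $x - (x - x_0)/\beta$
(`stiffness_center_estimate()`); a bilateral estimate averages the two
sides. Two consequences drive everything downstream: at $\beta = 1$
the models coincide exactly (so no experiment with linear springs can
separate them if the exponent is 1), and at $\beta < 1$ the stiffness
model predicts biases strictly smaller than bisection, shrinking to
zero — and eventually reversing — as probes go deeper.

**Adjudication.** The probe depth is unobservable, so the stiffness
model yields a *range* of predictions rather than a point. The package
therefore adjudicates the way the field does: compute the bisection
band by sweeping $F_{th}$ over the literature range 0.05–0.1 N
(`prediction_band()`), average measured biases across feedback
conditions, and compare magnitudes (`adjudicate()`). Biases inside the
band are consistent with bisection; biases systematically below it
favor stiffness extrapolation. The overall call requires more than
half of the informative (nonzero-band) conditions below the band. Only
the bisection model is ever fitted — fitting the stiffness model would
require committing to a probe-position assumption the data cannot
check.

## Tunable parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `F_th` | force detection threshold | N | 0.085 (bilateral), 0.12 (unilateral) generative defaults |
| `sigma_F` | SD of the threshold across trials | N | 0.052 / 0.062 |
| `sigma_P_fp`, `sigma_P_fa`, `sigma_P` | positional noise SD | m | 0.0093 / 0.012 / 0.0051 |
| `w` | right-side weight | — | 0.5, fixed |
| `beta` | power-law exponent | — | 0.8 |
| `F_th_range` | literature band | N | c(0.05, 0.1) |

The generative defaults (`default_bisection_params()`) are the
parameter values that reproduce typical human performance in the two
task variants; they are also exactly the values the round-trip
recovery exercise must return, which is what `scripts/acceptance.R`
verifies.

## The synthetic experiments

No raw data ship with the package; `generate_design()`,
`simulate_endpoints()`, `simulate_trajectory()` and `simulate_cohort()`
stand in for them.

*Designs.* The bilateral design crosses 7 stiffness pairs
((16,4), (16,8), (8,4), (4,8), (8,16), (4,16), (8,8) N/m) with 2
visual-feedback conditions; each condition places the field center
uniformly in three 2-cm regions spanning ±3 cm of the workspace middle
and draws one start distance of 1–3 cm per region, used once on each
side of the center — 84 trials per participant. The unilateral design
crosses K ∈ {4, 8, 16} N/m with spring side, 3 regions × 2 repetitions,
36 trials, starts always outside the virtual object. Whether start
sides alternate in the unilateral task is not constrained beyond
"outside the object", so the generator simply draws the distance per
repetition.

*Endpoints.* A trial's endpoint is `center + bias + N(0, sd)` with bias
and SD from the chosen generative model. The bisection generator uses
the model equations above. The stiffness generator places the mean at
the equal-force-probe extrapolation with the probe at the field edge by
default, and uses the positional noise alone as the endpoint SD: the
reported quantity is an extrapolated position estimate, so it inherits
the position sense's noise, while threshold noise has no direct path
into it. That SD choice is a modeling convention of the generator, not
a claim about human variability under the stiffness strategy.

*Trajectories.* Only summary statistics of real exploration are
available (about 10.9 s and 11 direction changes per bilateral trial;
8.5 s and 8 for unilateral), so trajectories are sinusoids around the
endpoint at the frequency implied by those medians, holding full
amplitude (at least 4 cm, so bilateral sweeps cross the center) for the
first third of the trial and then decaying exponentially to 0.1 mm —
"zooming in" — before settling exactly on the endpoint for a final
0.25 s hold. Force samples follow the field law at 250 Hz; a quality
flag (all-false by default, injectable with `flag_epoch()`) abstracts
the device's high-frequency-noise episodes. These trajectories emulate
timing, reversal counts and convergence, not kinematic realism: no
velocity profiles, grip-force channel, or device compliance. Passing
tests on them validates the *analysis chain*, not claims about human
movement.

*Random streams.* Each participant's design and endpoint noise use
independent substreams derived deterministically from the cohort seed,
so designs are identical across generative models at the same seed and
every artifact is reproducible from its manifest.

## Preprocessing rules

`preprocess_trials()` implements the analysis conventions for this kind
of experiment. The endpoint is the mean position over the trial's final
100 ms. Bilateral trial errors are referenced to the per-trial mean of
the force zero-crossings (linear interpolation between samples), the
best estimate of the field actually rendered; unilateral trials, whose
force is zero on one whole side, use the designed center. Outlier
rejection has two criteria, applied once and in order: (1) a flagged
run longer than 0.5 s — strictly longer, a run of exactly 0.5 s is
kept — rejects the trial; (2) a single leave-one-out pass per
condition rejects trial $i$ iff $|x_i - \bar x_{-i}| > 5\,s_{-i}$.
Criterion 2 is deliberately not iterated to convergence: iterating
would change rejection counts and the single-pass reading matches the
per-trial wording of the rule. In the degenerate case $s_{-i} = 0$, a
trial differing from an otherwise constant condition is rejected (its
deviation is infinitely many SDs). Condition summaries use the sample
SD ($n-1$); group summaries average biases and SDs across participants
unweighted, with the SE of the bias across participants.

One numerical caveat: linear interpolation across the stiffness kink of
an asymmetric bilateral field biases a single zero-crossing by up to
the inter-sample step (≈0.1 mm at 250 Hz and realistic speeds), so the
trajectory-level chain reproduces endpoint-level biases to about
10⁻⁴ m rather than exactly; the tests budget for this.

## Fitting

`fit_bisection()` minimizes
$SS = \sum_i (x_i - \mu_{x_i})^2 + (s_i - \sigma_{x_i})^2$ over the
nonnegative parameters — 4 of them against 28 numbers for the bilateral
design (both feedback conditions jointly), 3 against 12 for the
unilateral one. Adding bias and SD residuals in one objective is kept
exactly as stated for this model family; both terms are in meters so
the sum is well defined. Choices:

- **Optimizer.** Deterministic multi-start: a fixed grid of starting
  points spanning $F_{th} \in [0.01, 0.3]$ N, $\sigma_F \in [0.01,
  0.15]$ N and positional SDs up to 3 cm, each polished with `nlminb`
  (PORT) under box bounds $[0, 2]$ N for forces and $[0, 0.2]$ m for
  positional SDs. PORT was chosen over a derivative-free simplex
  because it honors bounds natively in base R; the objective is smooth,
  cheap (precomputed per-condition coefficients) and low-dimensional,
  so numerical gradients are unproblematic.
- **Scaling and tolerances.** The objective is internally scaled by
  10⁶ (m² → mm²-ish magnitudes) for conditioning; SS ties across starts
  within 10⁻¹² are broken by the lowest fitted $F_{th}$, and the
  reported `ss` is in m².
- **Convergence.** PORT reports "singular convergence" at
  flat-curvature optima (common when a noise parameter sits near 0);
  any *-convergence status, or agreement of two or more independent
  starts on the same SS, counts as converged. A fit where no start
  converges is returned with `converged = FALSE` and a warning, never
  silently.
- **Goodness of fit.** $R^2$ is the coefficient of determination over
  the concatenated (bias, SD) vector — the exact vector the objective
  minimizes — about that vector's grand mean. No formula for $R^2$ is
  canonical for a joint bias+SD fit; this one is the only choice
  consistent with the objective.

Self-consistency is the load-bearing validation: fitting
model-generated noiseless summaries recovers every generating parameter
to well under 0.1% (machine precision in practice), the optimizer never
loses to an exhaustive coarse grid search, and noisy 12-participant
cohorts recover $F_{th}$ with a median absolute error under 0.02 N
across 100 replicates.

```{r roundtrip}
dat <- bisection_predict(exp1_conditions(), default_bisection_params("exp1")) |>
  rename(bias_m = mu_x, sd_m = sigma_x)
tidy(fit_bisection(dat))
```

## Problem sizes and runtime

The validation suite uses 10⁴ endpoint draws per condition for the
generative-consistency checks (at that size, 3% of the response SD
equals three standard errors of the mean, which is the comparison the
tests apply to sample means; sample SDs are compared at 3% relative
error), 100 replicate cohorts of 12 participants for noisy recovery,
and grid oracles of roughly 10⁴–10⁵ points. The full suite runs in a
few minutes on one CPU; the acceptance script's round trips are
deterministic and finish in seconds.

## Known limitations

- The stiffness model is never fitted to data, only banded; any use
  beyond adjudication requires a probe-depth model the package does not
  provide.
- $F_{max}$ for probe sweeps uses the ±6 cm linear-field extent, so
  "deepest probe" means the deepest *equal-force* probe both springs
  can render inside the linear region (`min(K) × 0.06` N).
- The degenerate zero-SD leave-one-out rule and the single-pass
  semantics are conventions; other reasonable readings would change
  rejection counts on pathological data.
- Trajectory simulation targets summary statistics only; do not use it
  to study movement kinematics.
- $R^2$ values from other software will differ unless computed over the
  same concatenated vector.
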