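---
title: "Estimating blood alcohol content from smartphone gait sensing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood alcohol content from smartphone gait sensing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitbac)
```

## The problem

Alcohol measurably degrades gait: postural sway grows and step timing
becomes irregular. A smartphone carried in a pocket records exactly the
signals that capture this — tri-axial linear acceleration (gravity removed
by sensor fusion) and device attitude (roll, pitch, yaw Euler angles).
`gaitbac` implements a complete pipeline that regresses estimated blood
alcohol concentration (eBAC) on features of a short, standardized
tandem-gait walk (heel-to-toe, about five steps), recorded at 100 Hz for
30 s during hourly ecological momentary assessments (EMA) on weekend
evenings.

There are three scientific components: the eBAC label model, the gait
feature set, and the Bayesian-regularized neural network (BRNN) regressor.
A synthetic-data generator ties them together so the whole pipeline can be
exercised and validated without access to human subject data.

## eBAC from self-reported drinks

Labels come from the Matthews–Miller formula,

$$\mathrm{eBAC} = \frac{c}{2}\cdot\frac{GC}{\mathrm{weight}} - 0.017\,t,$$

with $c$ the number of standard drinks, $GC$ a gender constant (9.0 for
women, 7.5 for men, absorbing sex differences in body water), weight in
pounds, and 0.017 g/dL per hour the fixed alcohol clearance rate over $t$
hours of drinking. Values are clamped at zero: a metabolized-out subject
has BAC 0, not a negative number.

Three operational choices are not fixed by the formula itself and were
settled as follows:

* **Accumulation.** $c$ is the cumulative drinks reported since the
  episode's first nonzero report and $t$ the hours elapsed since that
  report. The alternative — anchoring $t$ at the start of the evening —
  would charge clearance for hours before any drinking, biasing every
  trajectory downward. An episode ends when eBAC returns to 0, after which
  the clock resets; this lets one evening contain two separated episodes.
* **Missing reports.** EMA completion in the emulated protocol is low
  (~32%). A missed hourly report contributes zero drinks, which
  systematically *under*-estimates eBAC; this conservative convention is
  the one appropriate when no other information exists.
* **Limb labels.** Each hour is tagged `ascending`/`descending`/`none` by
  comparing eBAC with the previous hour, so downstream analyses can
  stratify by the rising and falling phases of the alcohol curve.

```{r ebac}
p <- subject_profile("s1", "male", weight = 179)
compute_ebac(p, total_drinks = 4, hours_drinking = 2)
ebac_trajectory(p, drink_report_series("s1", "e1", 0:2, c(4L, NA, 0L)))
```

## Gait features

Each 30 s recording (3000 samples per channel) is cut into sliding
windows of 128 samples. The window length is the one setting the feature
definitions fix; the hop is not, and defaults to 64 samples (50% overlap),
the standard choice in the accelerometry activity-recognition literature
from which this feature set descends. Per window and axis we compute:

* **mean** — static posture/orientation component;
* **standard deviation** (population convention, dividing by $|w|$, so a
  constant window scores exactly 0) — sway magnitude;
* **pairwise inter-axis Pearson correlation** (xy, xz, yz) — captures how
  motion translates between axes; defined as 0 when either window is
  constant, avoiding NaNs on degenerate segments;
* **energy** — the sum of squared DFT coefficient magnitudes divided by
  the window length, $E = \frac{1}{|w|}\sum_k |X_k|^2$. By Parseval's
  theorem this equals $\sum_n x_n^2$, which the test suite uses as an
  independent oracle for the FFT path.

With 3 axes × (mean, SD, energy) + 3 correlation pairs per signal, and
two signals (acceleration, attitude), the descriptor has exactly
$12 \times 2 = 24$ entries. Reading "correlation" as inter-axis pairing is
the only convention that yields 24; per-window values are averaged across
windows to give one vector per walk, because the regressor consumes one
sample per labelled EMA. No trimming of pre/post-walk standing is applied
by default: the 30 s buffer is used as recorded.

## The Bayesian-regularized network

The regressor is a multilayer perceptron with one sigmoid hidden layer
and a linear output,
$$\hat y = b_0 + \sum_{j=1}^{H} w_j\,\sigma\!\Big(\sum_i W_{ji} x_i + b_j\Big),$$
linear at the output because eBAC values need not be confined to
$[-1, 1]$. One hidden layer suffices by universal approximation; the
pipeline offers cross-validated selection of $H$ over a 5–60 grid.

Training minimizes the regularized objective
$$F = \beta E_D + \alpha E_w, \qquad E_D = \sum_s r_s^2,\quad
E_w = \sum_p \theta_p^2,$$
by Levenberg–Marquardt: each step solves
$[\beta J^\top J + (\alpha + \lambda) I]\,h = \beta J^\top r - \alpha\theta$
with $J$ the analytic Jacobian of the predictions and
$r = y - \hat y$. Accepted steps (objective decreased) divide the damping
$\lambda$ by 10; rejected steps multiply it by 10 and re-solve, so the
update interpolates between Gauss–Newton (small $\lambda$) and gradient
descent (large $\lambda$). $\lambda$ starts at
$10^{-2}\max \mathrm{diag}(J^\top J)$, i.e. large relative to the
curvature, so early updates are conservative.

After every accepted step the evidence framework re-estimates the
hyperparameters from the Gauss–Newton Hessian of $F$,
$H = \beta\nabla^2 E_D + \alpha\nabla^2 E_w \approx 2\beta J^\top J + 2\alpha I$:
$$\gamma = N_{par} - 2\alpha\,\mathrm{tr}(H^{-1}), \qquad
\alpha \leftarrow \frac{\gamma}{2E_w}, \qquad
\beta \leftarrow \frac{n-\gamma}{2E_D}.$$
The factor 2 in $H$ matters: sum-of-squares Hessians are $2J^\top J$ and
$2I$, and only with them does $\gamma$ reduce to the eigenvalue form
$\sum_i \lambda_i/(\lambda_i+\alpha) \in [0, N_{par}]$ — the effective
number of parameters the data actually constrain. Dropping the 2 makes
$\gamma$ collapse to 0 on near-singular problems. $\gamma$ is clamped to
$[0, N_{par}]$ against round-off and $\alpha,\beta$ to $[10^{-12},10^{12}]$
to survive perfect fits ($E_D = 0$) and zero-weight states.

Numerical/initialization choices: weights start uniform in $[-0.5, 0.5]$
from the seed; $\alpha_0 = 0.01$, $\beta_0 = 1$; inputs are z-scored and
targets min-max scaled to $[0,1]$ before training (sigmoid units saturate
on raw feature scales; energies reach ~20 while correlations sit in
$[-1,1]$), with the statistics stored in the model and inverted at
prediction. Training stops at 300 iterations, a gradient norm below
$10^{-7}$, five consecutive iterations with $|\Delta\gamma| < 10^{-3}$, or
when no step can be accepted at the damping cap.

Two comparison trainers share the same machinery: plain LM fixes
$\alpha = 0,\ \beta = 1$ (so its trajectory is exactly the BRNN path with
updates disabled), and a Polak–Ribière conjugate-gradient trainer
minimizes $E_D$ with line search via `stats::optim(method = "CG",
type = 2)`. On small noisy samples the expected ordering — BRNN
generalizes best, plain LM overfits, CG trails — is asserted by a seeded
20-replicate experiment in the test suite.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *statistical structure* of a weekend-evening
EMA drinking study: 10 subjects (70% female, weights
$\mathcal N(179, 35^2)$ lb truncated above 80 lb), 8 evenings, five hourly
slots from 8 p.m. to midnight, each slot independently completed with
probability 0.32, roughly half of evenings involving drinking, and episode
totals from a rounded truncated normal with mean 3.6 and SD 2.2 on 1–10
drinks, spread over a contiguous block of 1–3 early-evening hours. These
defaults are the emulated study conditions, not tuning knobs. At these
settings the label distribution has mean ≈ 0.03–0.04 g/dL,
matching the protocol being emulated; the occasional light-bodied subject
drawing a 10-drink episode can exceed 0.3 g/dL, so only the bulk (99th
percentile) of the support is asserted to stay below ~0.3.

Gait recordings are built from a step-periodic anteroposterior
acceleration (fundamental 1.8 Hz plus two harmonics) whose phase is
jittered by a random walk, plus zero-mean lateral sway and slow roll/pitch
oscillation. Impairment enters multiplicatively: sway SD and phase-jitter
SD scale by $(1 + g\cdot \mathrm{eBAC})$ with gain $g = 10$ per g/dL — at
the observed peak of ~0.23 g/dL sway roughly triples, a deliberately
strong, clean coupling. White sensor noise (SD 0.02) is added to all six
channels. Labels attach the eBAC computed from the generator's
ground-truth drink series (impairment is driven by alcohol actually
consumed, not by what was reported); the missing-as-zero convention
applies when the eBAC module processes real report data.

What this generator does **not** emulate: biomechanically realistic gait,
phone-pose variability, per-subject tolerance differences, the empirical
growth of missingness later in the evening (a per-hour rate vector exists
but Bernoulli-independent missingness is the default), or any specific
quantitative gait–alcohol dose-response — the linear-variance coupling is
a stand-in chosen for testability. Consequently a high test R on
synthetic data demonstrates that the pipeline *recovers a monotone
coupling when one exists* and that no stage leaks labels (the
zero-coupling control must show no systematic correlation); it says
nothing about the attainable accuracy on real human gait.

## Evaluation conventions

Data are split 70/30 by sample, the pooled convention; because pooled
splitting lets models exploit subject identity, a `by_subject` grouping is
provided and recommended for generalization claims across people. The five
comparison metrics are Pearson R, MAE, RMSE, and the relative errors
RAE$= 100\sum|t-o|/\sum|t-\bar t|$ and
RRSE$= 100\sqrt{\sum(t-o)^2/\sum(t-\bar t)^2}$, both of which score the
mean predictor at exactly 100%; constant-target inputs make them (and R)
undefined and are flagged rather than propagated as NaN. Error histograms
use 20 equal-width bins over the error range. The baseline table pits the
BRNN against an RBF-kernel support-vector regressor (delegated to
`e1071::svm`, library defaults — a comparison row, not a contribution)
and ordinary least squares.

Problem sizes throughout the examples and tests — a 10 × 8-evening cohort
(~130 recordings), networks of 5–15 hidden units, 20-replicate Monte
Carlo — were chosen so that every experiment in the package, including the
full pipeline, reruns from scratch in minutes on a single core.

```{r pipeline, eval = FALSE}
res <- run_pipeline(simulation_config(seed = 1), n_hidden = 10, seed = 1)
res$metrics_test
res$comparison
```

## Known limitations

* The eBAC label is itself an estimate from self-report; the pipeline
  inherits every bias of the Matthews–Miller formula and of retrospective
  drink counting.
* Averaging window features over the full 30 s buffer mixes walking with
  any pre/post-walk standing; an activity-threshold trimmer would
  sharpen features but is deliberately off by default.
* The Gauss–Newton evidence approximation ignores second-order residual
  curvature; $\gamma$ is meaningful near a local optimum, less so early
  in training.
* LM solves a dense $N_{par} \times N_{par}$ system per step, so the
  trainer suits the hundreds-of-parameters regime it is used in here, not
  deep or wide architectures.
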