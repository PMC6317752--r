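---
title: "Simulating behavioral rigidity with aberrant sensory precision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating behavioral rigidity with aberrant sensory precision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sctrnn)
```

## The model

`sctrnn` implements a stochastic continuous-time recurrent neural network
(S-CTRNN) with parametric bias (PB) units, an embodied predictive-coding
agent. The network receives the current 10-dimensional sensory state
$x_t$ (8 joint angles and a 2-D ball position, each scaled to
$[-0.8, 0.8]$) and predicts both the mean $y_t$ and the variance $v_t$ of
the next sensory state. Five unit groups are connected in a fixed
topology: inputs, recurrent context units, PB units, output (mean) units
and variance units.

The context units are leaky integrators with shared time constant
$\tau = 4$:

$$
u_{t,i} = \frac{1}{\tau}\Big(\sum_j w_{ij} x_{t,j} + \sum_j w_{ij}
c_{t-1,j} + \sum_j w_{ij} p_{t,j} + b_i\Big) +
\Big(1 - \frac{1}{\tau}\Big) u_{t-1,i},
$$

with $c_{t,i} = \tanh u_{t,i}$. The PB units are the limiting case of an
infinite time constant: their internal state is constant across a forward
pass and acts as a low-dimensional "intention" code. Output and variance
units read the current context activations instantaneously; means are
$\tanh$-bounded and variances are $v_{t,i} = \exp(u_{t,i} + K) +
\epsilon$ with floor $\epsilon = 10^{-5}$. The constant $K$ is the
aberrant-precision manipulation: $K = 0$ is the normal condition and
$K \neq 0$ scales every estimated variance by $e^{K}$ above the floor.
The exponent argument is capped at 30 so the activation is total on
finite reals; the analytic derivative $e^{u+K}$ is kept past the cap so
a saturated variance unit can always be pulled back down by the
log-volume term.

All optimization minimizes the heteroscedastic Gaussian negative
log-likelihood per dimension and step,

$$
L_{t,i} = \tfrac12 \ln\big(2\pi v_{t,i}\big) +
\frac{(\hat y_{t,i} - y_{t,i})^2}{2 v_{t,i}},
$$

a precision-weighted prediction error: channels the network believes to
be noisy influence learning and inference less. At a fixed error $e$ the
optimum over $v$ is $v = e^2$, so the variance units learn the
observation noise.

## Learning, and a stability analysis

Offline learning fits all weights, biases, and one PB initial internal
state per training sequence by full-batch gradient descent with momentum
($\alpha = 10^{-4}$, $\eta = 0.9$) on the likelihood summed over
dimensions, steps and sequences, teacher-forced. Gradients are exact
back-propagation through time; the test suite checks them against
central finite differences to a relative error of $10^{-4}$, for full
parameters and for PB-only selectors, in open and closed loop.

One numerical choice deserves its own account. Applied literally to the
*summed* objective, the fixed $(\alpha, \eta)$ pair is unstable: the
curvature of $L$ in a variance unit's internal state at its optimum is
$0.5\,n_{\mathrm{terms}}$, where $n_{\mathrm{terms}}$ is the number of
(sequence, step) terms feeding that unit — about $2{,}300$ at our reduced
scale and $19{,}000$ at full scale — while momentum gradient descent is
stable only below $2(1-\eta)/\alpha = 2{,}000$. We therefore apply the
learning rate to the time-normalized gradient (the summed gradient
divided by the mean sequence length), which makes the update
scale-invariant in sequence length and stable at any scale; the loss
history still reports the raw sum. The momentum dynamics then oscillate
persistently around the optimum, so `train_offline(select = "best")`
keeps the parameters of the lowest-loss epoch instead of whichever point
of the oscillation the fixed epoch count happens to hit; the
optimization path itself is unchanged. The full-scale protocol
(`select = "final"`, 300,000 epochs) remains the default.

## Online adaptation (error regression)

During an interactive trial only the PB internal state is optimized,
online, over a sliding window of $W = 10$ steps. Each environment step
the network regenerates the window closed-loop — the first input takes
its proprioceptive part from the network's own earlier prediction and
its vision part from the observation at the window start; later inputs
are fed-back mean predictions — then accumulates the negative
log-likelihood of the *vision* channels against the observed ball
positions, and updates the PB state 20 times by the same
momentum-gradient rule (the rate again applies to the time-averaged
window gradient). The momentum buffer persists across the 20 iterations
and resets when the window advances. The regenerated window's first
context state is carried over as the boundary condition of the next,
advanced window — a postdiction: past states are reconstructed in the
light of current input. After the final iteration the network predicts
one step ahead; the joint part of that prediction is the motor command.

Two variants are exposed and off by default:

* `dims`: the adaptation objective can include all 10 output dimensions
  instead of the 2 vision dimensions. The default follows the
  experimental description (inference from visual feedback); the summed
  form is also implemented.
* `feedback_grad`: the window gradient can flow through the
  prediction-to-input feedback path. The default treats the regenerated
  window's inputs as given — with feedback the effective curvature of
  the window objective is much larger and the PB state chronically
  overshoots its optimum even in the normal condition, which we found
  turns healthy inference into saturation artifacts.

## The synthetic ball-interaction environment

The environment replaces the physical robot, camera and human partner.
Four behaviors are generated as sums of one or two sinusoids per joint
with behavior-specific amplitudes, phases and rest offsets, plus a 2-D
ball trajectory: *right* and *left* (ball rolled out to one side and
returned by the matching arm), *self-play* (a tight rolling loop
directly in front of the robot) and *attract* (both arms up-down while
the partner moves the ball on the far side). Training sets contain three
exemplars per behavior with i.i.d. Gaussian observation noise
($\sigma = 0.02$, about 1.25% of the sensor range) and ±5% length
jitter; nominal lengths are 1600/1900/1600/1200 steps, scaled by
`length_scale` for reduced profiles.

Design choices that matter, with reasons:

* **Periods** scale as $\sqrt{\texttt{length\_scale}}$ with a floor of
  10 steps ($\approx 2.5\tau$). A 1/8-length exemplar with full-scale
  periods would contain only ~5 cycles — far below the ~40-50 cycles of
  the full-scale recordings — which leaves the oscillation frequency
  badly determined; fully proportional scaling would leave too few steps
  per cycle for $\tau = 4$ integrators to resolve.
* **Amplitudes** sit mid-range ($|$nominal$| \le 0.45$). The physical
  robot reproduced its behaviors essentially perfectly at full scale; a
  faithful miniature should be reproducible by the reduced network to
  near its observation-noise floor, and pointwise regeneration error
  grows with trajectory amplitude at fixed phase accuracy.
* **Interaction contingency.** The partner entrains to the robot, as a
  human does: the return leg of *right*/*left* advances only while the
  commanded arm matches the nominal returning motion at a phase within
  ±10% of the period (`match_tol` 0.25 in max-norm); otherwise the ball
  waits at the robot's side and after 15% of a period the partner
  completes the return themselves. A mismatched robot therefore sees a
  stalled, error-inducing ball, while a matched robot sees the learned
  trajectory in lock-step with its own movement. *Self-play* and
  *attract* free-run (the partner demonstrates or drives the ball).
* **The self-play ball loop is tight** (radius ≲ 0.08 near the robot's
  front), so that a ball placed there is best explained by the
  self-play intention even before the robot rolls it.

What the environment does **not** emulate: ball physics, camera noise
statistics beyond i.i.d. Gaussian, the experimenter's judgement, or any
visual consequence of the robot's own arms. Passing tests on this
replica show that the inference-and-rigidity mechanism behaves as
described; they do not certify the original hardware results.

## Behavior classification

Generated joint series are assessed as follows:
pooled learned joint series are reduced to 2-D by PCA (deterministic
sign convention: the largest-magnitude loading of each component is
positive), occurrences are counted on a 20×20 grid over $[-N, N]^2$
($N$ = the maximum absolute projected value; if an assessed segment
exceeds it, the bound is enlarged and all histograms re-derived), and
segments are compared with each learned behavior by KL divergence.
A segment is *outwardly normal* if its divergence from the target
behavior is below $\xi$, half the minimum ordered-pair divergence
between learned behaviors. Otherwise the movement amount
$d = \frac{1}{T}\sum_t \sum_i |y_{i,t+1} - y_{i,t}|$ decides:
*freezing* ($d < 0.02$, no learned behavior close), *unlearned
movement* ($d \ge 0.02$, none close), *inappropriate learned movement*
($d \ge 0.02$, some non-target behavior close). The rule table leaves
one case open — $d < 0.02$ with a non-target behavior within $\xi$ —
which we label freezing, because movement has effectively stopped.

Two smoothing constants enter the KL computation. A pseudo-mass
$\lambda = 10^{-6}$ per bin keeps the divergence finite. At reduced
scale that is not enough: a learned histogram built from ~600 points on
400 bins misses, by sampling accident, bins inside its own noise band,
and a well-matched segment then pays a stray-bin penalty of order
$\ln(1/\lambda)$ — the same order as $\xi$ itself, so no $\lambda$ fixes
it. `behavior_library()` therefore applies one bin of 3×3 boxcar
(kernel) smoothing to every histogram before comparison
(`spatial_smooth = TRUE`). Full-scale learned series (thousands of
points per behavior) cover their noise band and would not need this.

## The experiments

`run_condition_grid()` reproduces the adaptability evaluation at
reduced scale: 10 networks trained from independent weight seeds on a
shared target set — each validated before entering the ensemble by
regenerating its own training sequences closed-loop (median
per-sequence worst-dimension RMSE below 0.1; a failed training run
redraws its weight seed by a fixed offset, up to three times). At
reduced scale a minority of weight seeds fail to reach a usable model
within the epoch budget; such a network misbehaves at *every* variance
level, which says nothing about precision and would never have been
carried into the original experiment, a working robot demonstrably
reproduces its trained behaviors in the normal condition. The screen
uses training fidelity only — no trial or classification outcomes.
The design: six mismatched initial-intention/situation
combinations (*left* or *right* intention crossed with the three other
situations), two trials each, at every $K \in \{-8, -4, 0, 4, 8\}$ —
120 trials per variance level, classified on steps 150–250. Per network
and level the analysis records the frequency of the three abnormal
labels combined and the mean windowed NLL per step; both responses go
into one-way repeated-measures ANOVAs (subjects = networks, conditions
= $K$ levels, df = (4, 36), no sphericity correction by default) and
Holm–Bonferroni-adjusted pairwise paired t-tests (the base test is our
choice; the adjustment itself is the fixed part of the analysis). The
ANOVA F is computed from the within-subject sums-of-squares
decomposition and cross-checked in the tests against
`aov(y ~ cond + Error(subj/cond))`.

Problem sizes used by the packaged tests and the acceptance script:
20 context units, 1/8-length sequences (about 150–240 steps), 10,000
training epochs, 250-step trials. At these sizes the full grid —
training ten networks and running 600 interactive trials — completes in
roughly a quarter of an hour on one core.

## Mechanisms you should expect to see

* $K = 0$: mismatched intentions are corrected within tens of steps;
  most trials classify outwardly normal.
* $K > 0$ (variance overestimated): precision-weighted errors shrink by
  $e^{-K}$, PB updates stall, the intention barely moves; the robot
  persists in context-inappropriate movement or freezes.
* $K < 0$ (variance underestimated): every residual error — including
  plain observation noise — is amplified; the PB state moves violently,
  can overshoot into $\tanh$ saturation where $(1 - p^2)$ annihilates
  further gradients, and fixes at inappropriate values while error
  remains large. Note the variance floor $\epsilon$ bounds the
  amplification: with learned variances near $\sigma^2 = 4\times10^{-4}$
  the effective precision gain at $K = -8$ is $\approx 40\times$, not
  $e^{8}$.
* Mean per-step NLL across a trial is lowest near $K = 0$ *when
  adaptation succeeds there*: perturbing $v$ away from the learned
  optimum raises the objective for matched errors. Residual adaptation
  failures at $K = 0$ carry very large NLL, while at $K > 0$ even failed
  trials have bounded NLL (errors are down-weighted), so this ordering
  is sensitive to the $K = 0$ success rate at reduced scale.

## Known limitations

* Closed-loop regeneration of a learned behavior accumulates phase
  error (~0.05 RMSE over ~15 cycles at the reduced profile; worse for
  roughly a quarter of weight seeds). This is phase diffusion, not shape
  error — the order-free histogram classifier is the appropriate
  fidelity measure at long horizons, which is precisely why the
  classifier works on histograms in the first place.
* Training quality varies across weight seeds; badly converged networks
  inflate abnormal rates at every $K$ and blur the $K = 0$ NLL minimum.
* The four behaviors and the partner model are explicit emulations;
  all quantitative results of this package are statements about this
  synthetic replica.
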