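# sctrnn

Simulating autistic behavioral rigidity with a stochastic
continuous-time recurrent neural network (S-CTRNN) with parametric bias.

## What this package is for

A prominent computational-psychiatry hypothesis holds that autistic
behavioral rigidity — freezing, restricted and repetitive movement,
resistance to change — can arise from *aberrant sensory precision*: the
brain systematically over- or under-estimating the reliability of its
sensory channels. This package provides a complete, desk-scale
simulation platform for that hypothesis, aimed at computational
psychiatrists and cognitive-robotics researchers: a predictive-coding
recurrent network that learns several sensorimotor behaviors, infers
which behavior its partner is engaged in by online prediction-error
minimization, and can have its estimated sensory variance artificially
scaled to produce — and let you quantify — rigid behavior.

The agent is an S-CTRNN with parametric bias (PB). Leaky-integrator
context units (time constant τ = 4) receive the current
visuo-proprioceptive state `x_t` (8 joint angles + 2 ball-position
coordinates in [−0.8, 0.8]) and predict the mean `y_t` *and variance*
`v_t` of the next state. Two PB units, constant within a forward pass,
encode the network's "intention"; different learned behaviors
self-organize to different PB values. Everything is trained by
minimizing the precision-weighted prediction error

```
L_{t,i} = ln(2π v_{t,i})/2 + (ŷ_{t,i} − y_{t,i})² / (2 v_{t,i})
```

by gradient descent with momentum (α = 1e-4, η = 0.9) and exact BPTT
gradients. During interaction only the PB state is re-optimized, 20
times per step over a sliding 10-step window of visual prediction
errors (*error regression* / postdiction). The manipulation
`v = exp(u + K) + ε` scales all estimated variances by `e^K`:
`K > 0` makes errors negligible (intention never updates), `K < 0`
amplifies them (intention overshoots and fixes in saturation) — two
routes to outwardly similar rigidity.

A synthetic ball-interaction environment stands in for the robot,
camera and human partner: four quasi-periodic behaviors ("right",
"left", "self_play", "attract") with an entrained partner model, a
KL-divergence histogram classifier labels generated movement
(outwardly_normal / freezing / unlearned_movement /
inappropriate_learned_movement), and an experiment driver runs the
networks × K-levels grid with repeated-measures ANOVA and
Holm–Bonferroni summaries.

## Worked example

Train a reduced-scale network on the four behaviors, then let it start
a trial intending "left" while the partner plays "attract":

```r
library(sctrnn)

specs   <- behavior_specs(length_scale = 1/8)
targets <- make_target_set(specs, n_per_behavior = 3, seed = 1)
config  <- network_config(n_context = 20)
model   <- train_offline(targets, config, seed = 1, epochs = 10000,
                         select = "best")
model

library <- behavior_library(targets)
sched   <- situation_schedule(0L, "attract", 250L)

for (K in c(-8, 0, 8)) {
  trace <- run_interactive_trial(model, sched, K = K, seed = 7,
                                 initial_behavior = "left", specs = specs)
  cls <- classify_segment(trace_joints(trace)[150:250, ], "attract",
                          library)
  cat(sprintf("K = %+d: %s (d = %.2f, KL to target = %.2f, xi = %.2f)\n",
              K, cls$label, cls$d, cls$kl_by_behavior[["attract"]],
              cls$xi))
}
```

which prints

```
<sctrnn_model> 20 context units, 2 PB units, 12 sequences, 10000 epochs
  final loss -5.576e+04 (initial 2.635e+04)
K = -8: outwardly_normal (d = 0.59, KL to target = 0.09, xi = 1.04)
K = +0: outwardly_normal (d = 0.60, KL to target = 0.08, xi = 1.04)
K = +8: unlearned_movement (d = 0.25, KL to target = 3.38, xi = 1.04)
```

At the normal precision level (K = 0) the error regression pulls the
intention to the situation and the generated movement matches the
learned "attract" histogram well within the threshold ξ. At K = +8 the
estimated variance is inflated about 3000-fold, prediction errors are
down-weighted to irrelevance, and the intention never leaves "left" —
the generated movement resembles no learned behavior at the imposed
situation. At K = −8 amplified errors can still produce successful
switching in an individual trial, as here; the elevated *rate* of
failures (overshoot and fixation of the intention in saturation) is a
statistical effect visible across the full trial grid below. The
movement amount `d` distinguishes freezing (d < 0.02) from moving
abnormal behavior.

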