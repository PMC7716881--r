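---
title: "Predictive-coding S-CTRNNs with developmental parameter modifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive-coding S-CTRNNs with developmental parameter modifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctrnn)
```

## The model

The stochastic continuous-time recurrent neural network (S-CTRNN) is a
leaky-integrator RNN that predicts, at every time step, both the **mean** and
the **variance** of its next input.  For a context layer of $C$ neurons with
internal state $u^{rec}_t$, activation $h_t = \tanh(u^{rec}_t)$ and input
$x_t \in \mathbb{R}^2$:

$$u^{rec}_t = \Big(1-\tfrac{1}{\tau}\Big)\,u^{rec}_{t-1}
  + \tfrac{1}{\tau}\big(W^{inp} x_t + W^{rec} h_{t-1}\big),$$

$$y_t = \tanh(W^{out} h_t), \qquad
  v_t = \exp(W^{var} h_t + K) + 10^{-5}.$$

The time constant $\tau \ge 1$ (default 2) sets how quickly the recurrent
layer tracks its input; the $10^{-5}$ floor keeps the predicted variance
strictly positive.  Each trajectory class $s$ owns a learned *initial state*
$u_0^{(s)}$, the recurrent state at $t = 0$; the initial state selects which
attractor the network settles into, so one network can draw several shapes.

Training minimizes the heteroscedastic Gaussian negative log-likelihood of
each step's prediction against the next input,

$$-\ln L^{out} = \sum_{t}\sum_{i}\Big(\ln(2\pi v_{t,i})
  + \frac{(x'_{t+1,i}-y_{t,i})^2}{2 v_{t,i}}\Big),$$

plus a distance prior that keeps the initial states spread around their mean
at variance $v_{dist}$ (default 10),

$$-\ln L^{init} = \sum_{s}\sum_{i}\Big(\ln(2\pi v_{dist})
  + \frac{(u^{(s)}_{0,i}-\hat u_{0,i})^2}{2 v_{dist}}\Big).$$

Both terms are summed without extra weighting, and $\hat u_0$ is recomputed
from the current states at every evaluation, so the prior is
translation-invariant.  All weights and initial states are updated by Adam
on the full batch each epoch.

## The two developmental parameters

**External contribution $\chi_{train} \in [0.1, 1]$.**  During learning the
network does not receive the raw trajectory.  It receives the *integrated
input*

$$x'_{t+1} = \chi_{train}\, x_{t+1} + (1-\chi_{train})\,(y_t + \nu), \qquad
  \nu \sim \mathcal N(0, v_t),$$

a mixture of the sensory signal and the network's own previous prediction,
perturbed with noise of the predicted variance.  The likelihood compares the
prediction against this integrated signal as well.  $\chi_{train} = 1$ is
purely sensory learning; small values make the network attend mostly to its
own prior.  At $\chi_{train} = 0$ the prediction error would be identically
zero and no learning could occur, hence the 0.1 lower bound.  At test time
the same mixing switches the network between *reactive* (open-loop,
$\chi = 1$) and *proactive* (closed-loop, $\chi = 0$) generation.

**Aberrant precision $K$.**  The offset inside the variance readout
($v = \exp(u^{var} + K) + 10^{-5}$) makes the network systematically
overestimate ($K>0$) or underestimate ($K<0$) the sensory noise during
learning.  Since the prediction error is precision-weighted
($e/v$ in the gradient), $K>0$ damps and $K<0$ exaggerates the
error-driven updates.  $K$ acts throughout learning, not on a mature
network.

Two design points deserve a note because the defining formulas admit two
readings:

* *Noise placement.*  We attach $\nu$ to the prediction term,
  $x' = \chi x + (1-\chi)(y+\nu)$, so that $\chi = 1$ reproduces the raw
  input exactly — required for the $\chi_{train}=1$ condition to be a clean
  control in which only the precision modification is active.  The literal
  unconditional form $\chi x + (1-\chi) y + \nu$ is available via
  `network_config(noise_placement = "literal")`.
* *Gradient flow.*  The integrated input, including its appearance as the
  likelihood target, is treated as data during backpropagation: no gradient
  flows through the mixing path into the previous step's prediction.  This
  matches the observation that $\chi_{train}=0$ yields no learning, and it
  makes the analytic gradients exactly equal to finite differences of the
  deterministic loss (verified to $10^{-4}$ relative in the test suite).
  At $t=0$ no prediction exists, so the first point of a sequence is fed
  unmixed.

## The drawing task

The synthetic task is drawing: eight two-dimensional trajectory classes,
an ellipse and a figure-eight at each of four positions (right, left, top,
bottom), 75 time steps containing three repetitions of the shape.  Ellipses
are parameterized as $(0.25\cos\theta, 0.15\sin\theta)$ and eights as the
Lissajous curve $(0.15\sin 2\theta, 0.25\sin\theta)$, centered at
$(\pm 0.5, 0)$ or $(0, \pm 0.5)$, traversed counter-clockwise from the
rightmost point.  This keeps every coordinate well inside the $(-1,1)$ range
of the tanh readout and makes same-position pairs overlap spatially, which
is what the representation analysis probes.  Gaussian observation noise is
added per class with variances $0.001, 0.001, 0.003, 0.003$ (ellipses) and
$0.005, 0.005, 0.007, 0.007$ (eights); their mean, $0.004$, is the floor
below which no honest prediction error can fall, and therefore the
reference value for "optimal" behavioral performance.  A training batch
holds every class `repeats` times, corrupted independently; the batch is
sampled once per run so that a run is reproducible from one seed, and the
first realization of every class is the recorded evaluation reference.

What the generator emulates is the *structure* of the study conditions
(shape/position layout, per-class noise schedule, cycle count); what it does
not emulate is any property of human drawing — pen dynamics, speed profiles,
segment ordering.  Conclusions from passing tests therefore concern the
model's representational dynamics on this abstract task, not behavior on
real drawing data.

## Evaluation

* **Behavior**: mean squared error of closed-loop generated trajectories
  against one recorded training realization per class
  (`prediction_mse`); the clean-reference MSE is available too.
* **Representation**: context activations ($C \times 75$ per class) are
  recorded during closed-loop generation.  All class pairs are compared by
  dynamic time warping (Euclidean local cost, no window, raw accumulated
  cost; the quotient below is invariant to the common normalizations, so
  the canonical variant is used).  Same-position pairs average into the
  *inner distance*, different-position pairs into the *outer distance*;
  their quotient is small for well-separated representations.  A PCA
  embedding of the pooled per-time-step activations (per network; pooling
  across networks of a condition is a flag away) gives the low-dimensional
  picture and the explained-variance fractions.
* **Generalization** (Experiment 2): networks are trained on seven of the
  eight classes (the bottom eight held out).  For each target an initial
  state is inferred with frozen weights — Adam on the open-loop likelihood,
  starting from the mean of the learned initial states — and the reactive
  one-step error from that state measures recognition.  Trained classes are
  re-inferred the same way for symmetry.  Inference uses the clean target
  by default.  The per-network Pearson correlation between the inner–outer
  quotient and the untrained-class error links representation quality to
  generalization.

## Sweep design

`run_experiment1()` and `run_experiment2()` sweep one parameter while
pinning the other: the $\chi_{train}$ sweep holds $K = 0$, the $K$ sweep
holds $\chi_{train} = 1$.  A master seed fans out deterministically into
per-trial sub-seeds such that all conditions of a trial share the same
initial weights and the same noisy dataset, while the prediction-noise
stream differs per condition; rerunning with the same master seed
reproduces every cell bit-exactly.  Diverged runs (possible at extreme
negative $K$) are recorded as failed and excluded from aggregates, never
retried.

## Full-scale versus desk-scale protocol

The full study protocol is 70 context neurons, batches of $8 \times 50$
noisy realizations, up to 30{,}000 training epochs at Adam step size 0.001,
5{,}000 inference epochs, 10 trials per condition, ten $\chi_{train}$
values and seven $K$ values.  Those are the package defaults
(`experiment_config()` with `scale_factor = 1`).

The test suite and the acceptance script run a *desk-scale* protocol chosen
once and kept fixed: 40 context neurons, 8 realizations per class, 3 trials,
a 3{,}000-epoch training cap, 500 inference epochs, and the condition
subsets $\chi_{train} \in \{0.1, 0.4, 1.0\}$ (plus $\{0.5, 1.0\}$ for the
generalization experiment) and $K \in \{-8, 0, +8\}$ (plus $\{-4, +4\}$).
Two step-size choices compensate the 10-fold shorter epoch budget:

* $\chi_{train}$ sweeps use step size 0.003.  Larger steps destabilize the
  $\chi < 1$ conditions, where the sampled prediction noise $\nu$ feeds
  back into the input and the gradient, and also destabilize late training
  at $\chi = 1$ once the predicted variance has collapsed onto the true
  noise level (each unit of variance underestimation multiplies the
  error-gradient, the overlearning regime).
* $K$ sweeps use step size 0.01, giving a total optimization distance
  (step size × epochs) equal to the full protocol's.  The $|K| = 8$
  conditions must first move the variance readout by $|K|$ log-units
  through bounded weights before ordinary mean learning resumes, which is
  exactly why these conditions need the longest training at full scale;
  with a smaller desk-scale step they never leave that ramp.

Even so, several full-scale phenomena do not survive the shrinking,
because they presuppose that *every* condition has been trained to
behavioral convergence:

* At $K = +8$ the behavioral catch-up (closed-loop error on par with
  $K = 0$) needs on the order of the full 30{,}000-epoch budget — the
  overestimating network first spends its budget renormalizing the
  variance readout — so at desk scale it remains behaviorally impaired,
  and its degenerate activations also scramble the $K$-ordering of the
  inner–outer quotient.
* At $\chi_{train} = 0.1$ an undertrained network inherits the geometry of
  its input (same-position trajectories are similar signals, so their
  activation time courses cluster), which makes the quotient artificially
  *low*; the full-scale impairment — drifting, poorly separated attractors
  — only appears once the network has actually learned the task.  The left
  arm of the representation U-shape therefore inverts at desk scale, and
  mid-$\chi$ runs remain behaviorally short of the noise floor.
* Within the short budget, noise *underestimation* ($K = -4$) has not yet
  paid off in generalization, so the full-scale ordering of the holdout
  errors across $K$ can invert, while the $\chi$-ordering (moderate
  $\chi$ generalizes better than $\chi = 1$) is already robust.

The corresponding acceptance checks flag exactly these clauses; they are
properties of the reduced budget, not of the model.  Likewise the printed
full-scale PCA
explained-variance levels (about 43% and 41% for the two sweeps) belong to
100+ networks trained to full convergence; at desk scale the suite checks
the structural properties of the embedding instead (fractions sum to one,
rank-2 data gives exactly two non-trivial components).

## Numerical choices

* Adam: $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$; step
  size as above, 0.001 by default.
* Convergence rule: every 100 epochs, compare the mean of the batch-mean
  per-sequence NLL over the last 500 epochs with the mean over the 500
  before; stop when the improvement is below 0.001 and the standard
  deviation over the last window is below 0.05.  Tracking the *per-sequence*
  likelihood (rather than per-element) keeps the rule from firing during
  the slowly drifting variance-ramp phase of large-$|K|$ runs, which must
  train longest.
* Weight initialization: i.i.d. uniform on $[-0.025, 0.025]$; initial
  states start at zero.  One initialization seed is shared across all
  conditions of a trial.
* All randomness (dataset noise, weight draws, prediction noise) flows
  through R's RNG, so `set.seed()` makes training bit-reproducible; the
  C++ core draws from the same stream.
* Non-finite losses abort the run with a diagnostic; the experiment
  drivers record such runs as failed.
* A degenerate normalization range (all condition values equal) is
  rejected rather than silently mapped.

## Limitations

* Single recurrent timescale; no hierarchical or parametric-bias variants.
* The likelihood pairs the variance of step $t$ with the target of step
  $t+1$ as the defining formula states; the alternative same-step pairing
  is not implemented.
* The inner-distance statistic needs at least one position represented by
  two classes; in the holdout experiment the held-out position contributes
  no inner pair.
* Desk-scale results are trend-level reproductions; exact figure-level
  values require the full protocol (`scale_factor = 1`), which takes CPU
  days, and remain outside the routine test budget.
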