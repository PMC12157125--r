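---
title: "Deep Cox modelling of imaging data: methods and design notes"
author: "coxcnn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep Cox modelling of imaging data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxcnn)
```

## The model

`coxcnn` implements an extended Cox proportional-hazards model in which the
log relative hazard of subject $i$ with image $x_i$ is the output of a
convolutional network $f(x_i; \Theta)$:

$$\lambda(t \mid x) = \lambda_0(t)\, e^{f(x;\Theta)},$$

with $\lambda_0$ an unspecified baseline hazard. Each subject contributes a
right-censored observation $(T^*_i, \delta_i)$ — the observed time
$T^* = \min(T, C)$ and the event indicator $\delta = 1\{T \le C\}$ — and,
for the two-task setting, a binary disease label $y_i$ predicted through
the sigmoid link $P_i = \mathrm{sigmoid}(f_i)$ from the *same* network
output.

Four training losses are defined directly on the score vector, so they
differentiate through any scoring model:

* **Full-batched loss** — the averaged negative log partial likelihood
  $-\tfrac1n \sum_i \delta_i [f_i - \log \sum_{j \in R(T^*_i)} e^{f_j}]$,
  with the inclusive risk set $R(t) = \{j : T^*_j \ge t\}$. It eliminates
  $\lambda_0$, is invariant to shifting all scores, and its risk-set sums
  span the whole dataset.
* **Mini-batched loss** — the same expression averaged over a random batch
  $\Omega$ with risk sets intersected with $\Omega$. With $\Omega$ equal to
  the full dataset the two losses coincide exactly (this identity is
  asserted to machine precision in the tests). The batch size can be as
  small as 2.
* **Oracle loss** — the full (not partial) negative log-likelihood
  $-\tfrac1{|\Omega|}\sum_{i\in\Omega} [\delta_i f_i - e^{f_i} T^*_i]$,
  valid only when the generating baseline is known to be
  $\lambda_0 \equiv 1$, as in the simulation designs. It retains absolute
  hazard scale (no shift invariance) and serves as the information
  upper-bound comparator.
* **Two-task loss** — the batched survival loss plus binary cross-entropy
  on $P_i$, sharing one output head.

The Breslow estimator provides the plug-in baseline: the increment at each
distinct event time $\tau$ is $d_\tau / \sum_{k \in R(\tau)} e^{f_k}$
(simultaneous events share one denominator), giving the survival predictor
$S(t \mid x) = \exp(-\hat\Lambda_0(t)\, e^{f(x)})$. With all scores zero
the estimator reduces to Nelson–Aalen, which the tests verify against the
`survival` package.

### Risk-set convention

A strict reading of $R(t) = \{i : T^*_i > t\}$ would exclude a subject from
its own risk set at its event time, making the partial-likelihood terms
ill-defined for the last event. We use the inclusive convention of the
classical Cox likelihood, $R(t) = \{i : T^*_i \ge t\}$, together with
Breslow handling of tied event times.

### Evaluation

The concordance index enumerates pairs $(i, j)$ with $T^*_i > T^*_j$ and
$\delta_j = 1$; a pair is concordant when $f_i < f_j$. Censored-versus-
censored pairs and tied-time pairs are never evaluable. Tied *scores*
count $0.5$ under the default `half` policy — the convention under which
uninformative constant predictions score exactly $0.5$ and under which a
class-constant oracle scorer attains the theoretical value derived below —
or $0$ under the literal `strict` policy, kept as an option. The subgroup
index C2 restricts the dataset and scores to the subgroup (event cases in
design B, the cancer group in design C) *before* pair enumeration. AUC is
the Mann–Whitney rank statistic.

## Synthetic benchmark designs

The generators reproduce the statistical structure of the studies the
losses are meant for, with every unstated knob fixed once at a realistic
value and recorded here. All stages draw from substreams derived
deterministically from one master seed.

### Two-class designs (A: uncensored, B: censored)

Two visually distinct 28×28 grayscale classes (a ring and a bar with
jitter, intensity variation and background noise — surrogates for a pair
of easily separable natural-image classes; a plain linear classifier on raw
pixels reaches ≥ 99% accuracy, which the tests assert). Survival times are
exponential with rate $e^{\phi_j}$ on a unit baseline. The class log
relative hazards default to $\phi = (0, 3)$: with class-constant scores,
uncensored times, and tie weight $0.5$ the expected concordance is

$$C = q\,\frac{e^{\Delta}}{1+e^{\Delta}} + \frac{1-q}{2},
  \qquad \Delta = \phi_1 - \phi_0,$$

where $q$ is the between-class fraction of pairs; at class balance and
$\Delta = 3$ this gives $C \approx 0.726$, the reference oracle value for
the uncensored design. `theoreticalCIndex()` computes this quantity and a
property test checks the empirical agreement at $n = 2000$.

**Censoring (design B).** Half of the subjects whose observed time exceeds
the *cohort* median are relabelled censored, the random halving drawn
independently within each class; observed times are left unchanged. The
choice of the cohort median (rather than each class's own median) is
deliberate: with $\Delta = 3$ the long-lived class loses many of its large
event times (≈ 45% censored) while the short-lived class is barely touched
(≈ 5%), which is exactly what makes the all-pairs index C1 exceed the
event-only index C2 in this design. A per-class median would censor both
classes equally and reverse that ordering — an easy way to get the
qualitative behaviour of this benchmark wrong.

### Nodule design (C)

32×32 RGB images on randomized textured backgrounds. Every image receives
40–60 small black or white dots of 1–2 px (benign nodules) and a few
smooth bright blobs (1–3 per image, peak 0.75–0.95) that mimic the natural
white areas of photographic backgrounds — without them the white-patch
signal is separable from brightness alone and classification becomes
unrealistically easy. Images are assigned to the cancer group with equal
probability; cancer images additionally receive exactly two uniform white
patches, sized 8–14 px for event cases and 5–8 px for the 50% of cancer
cases randomly labelled censored; non-cancer cases are all censored. Each
sample's survival time is exponential with log relative hazard
$\phi = 0.25 \cdot \text{(largest nodule size in px)}$, so time decreases
stochastically with nodule size; censoring flips only the event label.
The full generative ledger (class, $\phi$, time, event, label, largest
nodule size) is emitted alongside the images and round-trips losslessly
through CSV.

### What the generators do not emulate

Surrogate textures replace natural image statistics; dots and patches are
axis-aligned squares rather than irregular nodule shapes; hazards depend
on a single size summary. Passing benchmarks therefore demonstrates that
the losses, metrics and training loop behave as designed on data with the
paper-described generative structure — not that any particular clinical
performance would be attained on real CT cohorts.

## Architectures

Five reference builders reproduce published layer tables as hard shape
contracts: the two simulation CNNs (28×28×1 trunk with dense
1024→128→1; 32×32×3 trunk with dense 100→10→1 whose single output feeds
both tasks), and three 3D feature extractors for 96³ CT nodule crops
(AlexNet-, VGG16- and ResNet-18-style, each ending in a 128-feature
vector), plus the five-crop integration head (shared dense 128→32 per
crop, per-crop max, concatenation to a 5-vector, dense 5→1). Each builder
composes its layers symbolically and fails, naming the offending layer, if
the computed trace deviates from the reference table.

Where the tables leave hyperparameters unstated we fix conventional
choices: rectifier activations after every convolution and hidden dense
layer with linear final outputs; no normalisation in the plain stacks but
pre-activation batch normalisation inside residual blocks; the 3D AlexNet's
strides/paddings are the unique conventional assignment reproducing the
printed spatial trace 48→23→23→11→9→9→4 (first convolution stride 2,
same-padded; 3³ pools stride 2 unpadded); the VGG pools are 3³ stride-2
with padding 1 so each pool exactly halves the side. Weights use seeded
variance-scaled fan-in initialisation.

The network engine stores arrays column-major with samples last,
implements convolutions as im2col + GEMM in single precision (the
conventional arithmetic for CNN training; all loss and metric code is
double precision), and verifies its backward passes against central finite
differences in the tests.

## Training loop

Plain SGD with momentum 0.9 and learning rate 0.01 by default — the source
studies state only that stochastic gradient descent was used — with
gradients clipped to a global L2 norm of 5, a safeguard that leaves
ordinary updates untouched (typical norms are well below 1 after the first
few batches) but prevents the occasional exploding early step from pushing
the network into a dead-rectifier state.

Each epoch partitions the data into disjoint random batches (so every
sample contributes once per epoch); a trailing singleton batch is merged
into its predecessor; batches that happen to contain no events contribute
nothing to the survival loss and are counted, not errored. Within-batch
risk sets are recomputed from the batch members' observed times at every
evaluation. For the full-batched objectives an epoch is one *exact*
full-data gradient step, computed in two passes (a cache-free forward for
the scores, then a chunked backward); the mini-batched regime therefore
performs ~n/batchSize updates per epoch against one, which is why it
settles in fewer epochs — the engine tests assert this via the held-out
loss after the first epoch. Held-out evaluation always uses the full test
set with the full-batched value of the trained loss family, plus the
concordance/AUC metrics.

Because a full-batch "epoch" is a single exact step, the drivers give
that regime a larger base rate (0.1) run with a three-epoch linear warmup
and a bold-driver safeguard: when the exact loss decreases the rate
regrows by 10% (capped at its configured value), and when it increases
the step is undone, the rate halved and the momentum restarted. This
combination survives the early transient that a fixed large step does not,
while still making visible progress in ten to fifteen exact steps. An
adaptive-moments optimizer (`optimizer = "adam"`) is available in the
training configuration; on these batch-normalisation-free stacks its
uniform per-parameter steps proved prone to collapsing the rectifier
units at usable rates, so the drivers keep safeguarded momentum SGD.

## Problem sizes

The simulation drivers default to the benchmark sizes of 10,000 training
and 1,000 test samples. The acceptance script and the end-to-end tests run
the same experiments at 4,000/1,000 with 8 epochs (designs A/B) and 12
mini-batched / 15 full-batched epochs (design C), batch size 64 — sizes at
which the trained concordance indices sit well within the sampling noise
of the full-size runs while a complete reproduction stays comfortable on a
single CPU core. Fifteen exact gradient steps are not enough for the
full-batched two-task variant to reach its converged cancer-group
concordance (the mini-batched variant, with ~60 updates per epoch,
converges well inside its budget); the acceptance suite states the
converged bound for both variants and the full-batched one is expected to
fall short of it at these step counts.

## Numerical choices and degenerate inputs

Risk-set log-sum-exp terms are max-shifted; sigmoid outputs are clamped to
$[10^{-12}, 1-10^{-12}]$ inside the cross-entropy; a dataset or batch
without events has survival loss 0 by definition; the concordance index
errors when no pair is evaluable; an event observed at a time carrying no
baseline-hazard increment is an error (log of zero). Ties: tied event
times share a Breslow denominator; tied scores follow the declared tie
policy; tied observed times are never evaluable pairs.

## A structural note on C1 versus C2 in the nodule design

In the nodule design the all-pairs concordance C1 cannot fall below the
cancer-group C2 for any scorer that ranks by apparent nodule size. C1's
evaluable pairs are C2's plus the (non-cancer *i*, cancer-event *j*)
pairs, and non-cancer apparent sizes are stochastically no larger than
censored-cancer apparent sizes by construction, so the added pairs are at
least as concordant as C2's. Reported orderings with C2 above C1 arise
under a different pair-handling convention — scoring pairs whose
shorter-time member is censored as one half instead of excluding them —
whereas this package follows the strict evaluable-pair definition
throughout.

## Known limitations

No Efron tie correction, time-varying covariates, competing risks or left
truncation; no time-dependent AUC or confidence intervals for the metrics;
the 3D extractors are validated for shape, finiteness and gradient flow
but are not trained end-to-end by the test suite (a single 96³ crop takes
seconds per pass on CPU); training is single-threaded CPU SGD, adequate
for the bundled benchmarks rather than for full-scale 3D cohorts.
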