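# coxcnn

Deep Cox proportional-hazards modelling for imaging data: convolutional
networks as log relative-hazard scorers, trained by partial-likelihood
losses, with joint disease classification through a shared output head.

## The problem

Given right-censored survival data $(T^*_i, \delta_i)$ attached to images
$x_i$ — and, optionally, a binary disease label $y_i$ — the package models
the hazard as

$$\lambda(t \mid x) = \lambda_0(t)\, e^{f(x;\Theta)},$$

where $f$ is a CNN. Training minimises one of four interchangeable losses
defined directly on the score vector:

* the **full-batched loss**, the averaged negative log partial likelihood
  $-\frac1n \sum_i \delta_i \big[f_i - \log \sum_{j \in R(T^*_i)} e^{f_j}\big]$
  with inclusive risk sets $R(t) = \{j: T^*_j \ge t\}$;
* the **mini-batched loss**, the same expression over a random batch with
  risk sets restricted to the batch (equal to the full-batched loss when
  the batch is the whole dataset; batches as small as 2);
* the **oracle loss** $-\frac1{|\Omega|}\sum_{i\in\Omega}
  [\delta_i f_i - e^{f_i} T^*_i]$, usable when the generating baseline is
  known to be the unit rate (as in simulation), the information
  upper-bound comparator;
* the **two-task loss**, batched survival loss plus binary cross-entropy
  on $P_i = \mathrm{sigmoid}(f_i)$ from the same output.

The Breslow estimator supplies the baseline
($\Delta\hat\Lambda_0(\tau) = d_\tau / \sum_{k \in R(\tau)} e^{f_k}$, hence
$S(t\mid x) = e^{-\hat\Lambda_0(t) e^{f}}$), and evaluation uses the
censoring-aware concordance index (pairs $T^*_i > T^*_j$, $\delta_j = 1$;
concordant when $f_i < f_j$; tied scores worth 0.5 by default) plus rank
AUC for classification.

The package also ships seeded generators for three synthetic image-survival
benchmarks (two separable classes with exponential hazards, uncensored or
median-censored; and a nodule-image design whose hazards grow with nodule
size under two-level censoring), reference CNN builders with hard layer-
shape contracts (two 2D simulation nets; 3D AlexNet/VGG16/ResNet-18-style
extractors for 96³ CT crops; a five-crop integration head), and a seeded
SGD training engine — so every loss and metric is testable end to end with
no external data.

## A worked example

```r
library(coxcnn)

## survival core on a tiny cohort
ds <- survivalDataset(time = c(1, 2, 3), event = c(1, 1, 1))
hazardIncrements(breslowEstimator(ds, scores = c(0, 0, 0)))
#> [1] 0.3333333 0.5000000 1.0000000          # Nelson-Aalen at zero scores
fullBatchedLoss(survivalDataset(c(1, 2), c(1, 1)), c(0, 0))
#> [1] 0.3465736                              # log(2) / 2
concordanceIndex(ds, c(3, 2, 1))
#> [1] 1                                      # perfect reverse ordering

## a scaled-down censored benchmark run (design B)
res <- runSimulationB(nTrain = 1000, nTest = 500, epochs = 4,
                      losses = "mini_batched", seed = 1)
res$reports$mini_batched
#> MetricReport
#>   C-index (all samples): 0.7436 over 107762 evaluable pairs
#>   C-index (subgroup):    0.7083
```

The all-pairs C-index (C1) lands above 0.7 while the event-only C-index
(C2) is lower — the signature of the median-censoring design, where the
long-lived class loses many large event times. The theoretical ceiling for
the uncensored design is `theoreticalCIndex(c(0, 3), n0, n1)` ≈ 0.726 at
class balance.

A command-line driver for the simulations and for training on external
survival-table + image-container inputs is installed at
`inst/cli/coxcnn-sim.R` (subcommands `sim-a`, `sim-b`, `sim-c`, `train`,
`evaluate`).

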