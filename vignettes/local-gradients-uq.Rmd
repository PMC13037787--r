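---
title: "Local gradients as a region-wise uncertainty measure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local gradients as a region-wise uncertainty measure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gradUQ)
```

## The method

A trained segmentation model with parameters $\theta$ emits per-voxel
class probabilities; connected components of the arg-max label map are
the *localized regions* for which we want one uncertainty value each.
The idea is to measure how sensitive each region is to the learned
parameters: a region whose description changes a lot under infinitesimal
parameter perturbation is one the model is unsure about.

The sensitivity is realized by backpropagating a scalar **regional
target** $T_R$ computed from the predicted-class softmax probabilities
$p_i$ of the $N$ voxels in region $R$. The default target is the
voxel-averaged KL divergence against the uniform reference $q = 1/C$:

$$T_R = \frac{1}{N}\sum_{i=1}^N p_i \ln\frac{p_i}{1/C},$$

which is zero when every voxel is maximally ambiguous and grows with
confidence. The alternative target is the regional mean probability
$\mathrm{MP} = \frac1N\sum_i p_i$. Backpropagating $T_R$ and collecting
the gradients on a chosen subset $\varphi$ of decoder convolutional
blocks gives the Local Gradients score

$$LG(x)_R = \Bigl\lVert \tfrac{\delta T_R}{\delta \varphi} \Bigr\rVert_1 ,$$

one backward pass per region, each independent of the others. Scoring is
strictly post hoc: parameters are never updated, so predictions are
bit-identical before and after (the test suite asserts this).

Raw LG scores are unbounded and model-specific, so they are normalized
by the 95th percentile of scores from regions with a priori low
uncertainty, $U_{LG} = LG / P95\{LG_{low}\}$. The two non-gradient
baselines are put on the same direction-aligned scale by negation:
$U_{MP} = -\mathrm{MP}/P95\{\mathrm{MP}_{low}\}$ and
$U_{KLD} = -\mathrm{KLD}/P95\{\mathrm{KLD}_{low}\}$. After
normalization, *larger always means more uncertain* for all three.

## Interpretation choices

**Which probability enters the target.** $p_i$ is the scalar probability
of the voxel's predicted (arg-max) class, not the full class
distribution. For multi-class models the region's class channel is the
one the region was predicted as; it is frozen from the unperturbed
forward pass when gradients (or finite differences) are computed, which
keeps the target a fixed differentiable function of the parameters.

**Logarithm.** Natural log. The choice of base only rescales all scores
jointly and cancels in the P95 normalization.

**Clamping.** Probabilities are clamped to $[10^{-12}, 1]$ before the
log. Arg-max probabilities of a $C$-class softmax are $\ge 1/C$, so the
clamp is inert in practice; it exists to make the function total.

## Gradient targeting

Decoder convolutional blocks are the unit of targeting, named
`Block_<level>-<pair>` with level 0 adjacent to the bottleneck and two
blocks per resolution level; for a 5-level decoder the registry runs
`Block_0-0` … `Block_4-1`. The default group set is the pair nearest
the output (e.g. `Block_4-0`, `Block_4-1`): gradients close to the
output are cheapest to compute and targeting decoder parameters still
captures encoder sensitivities, because encoder activations re-enter the
decoder through the skip connections. "All learnable parameters of a
block" means its weights and biases. The block-sensitivity sweep
(`blockSensitivitySweep()`) scores every single block and every level
pair under both targets, with the two no-gradient baselines as reference
rows; one backward pass per region and target serves all configurations,
since the per-block L1 norms are additive over disjoint blocks.

## The toy network

No deep-learning backend exists in this R stack, and the gradient
computation *is* the contribution, so the package implements a miniature
2-D U-Net-style network with explicit forward and backward passes:
3×3 convolutions (zero padding), ReLU, 2×2 max pooling, nearest-neighbour
upsampling, skip concatenation, a 1×1 output convolution and softmax.
Blocks are plain conv + bias (the clinical models' instance
normalization is omitted; the method does not depend on block
internals). Inputs are z-scored per image — the standard
zero-mean-unit-variance preprocessing — which also keeps training stable
across the phantom contrast range. Training minimizes the sum of soft
Dice (over foreground classes) and cross-entropy with Adam, one image
per step; initialization, shuffling and therefore the final weights are
fully determined by the seeds.

The default configuration (2 levels, base 4 channels, 2 classes) has
4 574 parameters — small enough that *every* gradient the package
computes can be cross-checked against a central finite-difference
oracle. The oracle uses $h = 10^{-5}$: large enough that double-precision
cancellation is negligible, small enough that perturbations essentially
never cross a ReLU/max-pool kink, where the network is not differentiable
and central differences are biased (at $h = 10^{-4}$ such a crossing is
occasionally visible at the $4\times10^{-3}$ relative level; at
$h=10^{-5}$ agreement with backpropagation is at the $10^{-11}$ level).

The toy model is 2-D. Regions, degradations and NIfTI I/O all support
3-D; the method itself is dimension-agnostic because it only consumes
flattened voxel index sets. Whole-image forward passes replace the
sliding-window patch inference of production models.

## Calibration

`calibrateReference()` computes the percentile with linear interpolation
between order statistics (the `quantile()` type-7 convention — the
convention is documented because "95th percentile" alone does not pin it
down). Calibration is per trained model and per measure. Two reference
sources are supported by the same interface: non-degraded validation
predictions (appropriate when predictions are overwhelmingly correct)
and true-positive regions (appropriate when false positives are
frequent); the bundled experiments use TP regions. A degenerate
reference ($P95 \le 0$, e.g. all-zero scores) is an error rather than a
silent division.

One subtlety is worth recording. For a single voxel with
$p = \sigma(w)$, the gradient magnitude of the KL target is
$g(p) = (\ln 2p + 1)\,p(1-p)$, which *peaks near* $p \approx 0.65$: it
increases as confidence drops from 0.99 to ~0.65, then rolls off
slightly towards $p = 0.5$ because the saturation factor $p(1-p)$ caps
at 1/4 while the target derivative $\ln(2p)+1$ keeps shrinking. A
per-voxel confidence ramp therefore cannot be strictly monotone in
$U_{LG}$ all the way to $p=0.5$. The direction-alignment check instead
uses a mixed-composition family — a fraction $f$ of ambiguous voxels
($p=0.51$) among confident ones ($p=0.99$), mean confidence spanning
0.99→0.51 — for which all three normalized measures are strictly
increasing analytically. Real regions behave like mixtures (uncertain
boundaries around confident cores), which is why the direction holds
empirically in the end-to-end experiments.

## Degradation operators

Three operators, each swept over 11 evenly spaced magnitudes starting at
0 (the $\sigma=0$ element is the input, bit-exactly):

* additive Gaussian noise $I + W$, $W \sim \mathcal N(0,\sigma)$,
  $\sigma \in [0, 70]$ in image intensity units;
* additive speckle noise $I + W * I = I(1+W)$, $\sigma \in [0, 1]$
  (relative);
* Gaussian smoothing $I \otimes K$, $\sigma \in [0, 4]$ voxels,
  separable kernel truncated at $4\sigma$, reflective boundaries, kernel
  normalized to sum 1 (a constant image is preserved exactly).

The noise $\sigma$ values are interpreted in intensity units (the
smoothing $\sigma$ is the only spatial one); on the CT-like intensity
scale of the phantoms (background noise sd 20, lesion contrast 120–300)
the upper end of the additive-noise grid is severely degrading without
obliterating every lesion. Per-magnitude noise fields are independent
draws whose seeds derive deterministically from the sweep seed, so a
sweep is bit-reproducible from `(image, spec)` while magnitudes remain
independently perturbed.

## Regions, matching, metrics

* **Connectivity**: face adjacency (4-neighbourhood in 2-D, 6 in 3-D) by
  default, `face-edge-corner` available. Component ids are assigned by
  the row-major rank of each component's first voxel, making extraction
  deterministic.
* **Volume filter**: physical, `volume_cm3 = n_voxels × ∏spacing / 1000`,
  default threshold 0.25 cm³ in the pipeline entry points, matching the
  standard small-region post-processing rule.
* **TP/FP**: a predicted region is a false positive iff it shares *zero*
  voxels with nonzero truth; one voxel of overlap makes it a true
  positive. No minimum overlap fraction is imposed.
* **Matching across degradation magnitudes**: greedy full-overlap
  enumeration — every baseline region is matched to all regions it
  overlaps by ≥1 voxel (one-to-many, accommodating splits). When a
  region splits, the fragments' uncertainty values are combined by a
  volume-weighted average. Only *persisting* regions (matched at every
  magnitude) enter the degradation analysis; the response curve is the
  median over tracks of the per-track percent difference
  $100\,(U_\sigma - U_0)/U_0$, with IQR error bands.
* **Group comparisons**: percent difference of group medians,
  $100\,(\tilde U_A - \tilde U_B)/\tilde U_B$ (groups are unpaired).
* **ROC AUC**: Mann–Whitney form, ties credited ½; FP regions are the
  positive class. **FPR95**: regions are flagged when their uncertainty
  is ≥ a threshold; the threshold is the highest value still capturing
  ≥95 % of FP regions, and FPR95 is the fraction of TP regions flagged
  at it. **Rank tests** delegate to `stats::wilcox.test()` (exact
  distribution for small untied samples); the all-tied paired case
  returns the sentinel p = 1.

## The synthetic world

The phantom generator emulates the aspects of lesion-delineation data
the method interacts with: blob-like foreground lesions of varying size
(radius 3.2–6 voxels) and contrast (120–300 over a noisy zero-mean
background, sd 20) on a 48×48 grid at 4 mm spacing; optional smaller
distractor blobs (radius 2.2–3.4, one per image with probability 0.5)
drawn from the *same* contrast distribution but labelled background —
the analogue of benign mimics. Because the distractor and lesion size
ranges nearly touch, a trained model produces genuine false positives
rather than artifacts of label corruption. Multi-class phantoms assign
lesion classes to disjoint contrast sub-bands so classes are learnable.

What it does **not** emulate: anatomy and organ context, scanner
physics (CT sinogram noise, PET reconstruction), 3-D acquisition
geometry, inter-observer label noise, or class imbalance at clinical
scale. A green end-to-end test therefore establishes that the method's
machinery behaves as designed (direction of response, separability,
reproducibility) at desk scale — not that clinical effect sizes
transfer.

The standard fixture trains the 2-level network on 200 phantoms and
evaluates on 60 held-out ones; the degradation response uses 48 of them
(roughly a hundred persisting tracks — comparable statistical power to
the corresponding clinical experiment, which had 62 tracks from 27
images). The block-sensitivity fixture uses a 5-level decoder on 64×64
phantoms whose distractor radii (2.6–4.2) overlap the lesion range, so
both TP and FP regions exist for any seed — without both classes the
sweep's metrics are undefined.

## Numerical and degenerate-input choices

* Probability clamp $10^{-12}$; softmax computed with row-max shift.
* Ties in the arg-max label map break towards the lowest class index;
  the majority-truth-class vote excludes background when any nonzero
  class is present and breaks ties towards the smallest class; a region
  entirely on background is "unmatched" (`NA`).
* An empty region, an empty group list, a region off the output grid, a
  grid mismatch, a non-integer label map and a degenerate calibration
  all raise immediate errors rather than propagating NaNs.
* Percent differences with a zero baseline (or zero group median) are
  errors, matching their mathematical undefinedness.
* Model checkpoints are JSON with 17 significant digits, which
  round-trips IEEE doubles exactly; phantom/sweep/training seeds are
  derived from user seeds with a fixed integer recurrence kept below
  $2^{31}$.

## Known limitations

* The gradient measure is not a calibrated probability; it orders
  regions by sensitivity and needs the P95 reference set to be
  interpretable across models.
* Per-voxel, the gradient response rolls off very close to $p = 0.5$
  (see the calibration section); in practice region-level mixtures mask
  this, but a pathological region composed entirely of near-0.5 voxels
  would be mildly under-ranked.
* The method only scores regions the model predicted: false negatives
  cannot be recovered, by design of the post hoc contract.
* Computation scales with the number of predicted regions (one backward
  pass each).
* The toy network is 2-D and small; it exists to make the method's
  properties testable end-to-end, not to model clinical performance.
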