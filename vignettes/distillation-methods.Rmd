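---
title: "Stage-wise knowledge distillation for imbalanced image classification: methods and design"
author: "kdistill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise knowledge distillation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Classifying histopathology-like photographs of tumour specimens into fine
subtypes (here the five-class vocabulary Grade 1/2/3, AIS, MIA used for
lung adenocarcinoma) poses two coupled difficulties: the class distribution
is severely skewed (the reference cohort has 41 vs 1,317 images in its
extreme classes), and compact convolutional classifiers underfit the
fine-grained texture differences. Knowledge distillation addresses both: a
higher-capacity *teacher* network, trained first, supervises a *student*
through signals richer than one-hot labels, and that supervision is most
valuable exactly for the rare classes, where hard labels carry the least
information.

`kdistill` implements this teacher-student scheme in a backbone-agnostic
way. Both networks are partitioned into four corresponding *stage blocks*
(the hierarchical 4-stage layout shared by modern CNN and windowed
transformer families, with cumulative downsampling 4/8/16/32), and the
student is trained under a combined objective with three terms.

## The objective

Writing $z_s, z_t$ for student and teacher logits, $f_s^{(k)}, f_t^{(k)}$
for the stage-$k$ feature maps, and $y$ for the true class:

1. **Stage-wise feature matching.** Each student stage output is projected
   into the teacher's channel space by a learnable pointwise (1×1)
   adapter $\phi_k$ and compared by squared error,
   $L_1 = \tfrac14 \sum_{k=1}^4 \mathrm{MSE}\!\left(\phi_k(f_s^{(k)}),
   f_t^{(k)}\right)$.
   The teacher side is untransformed: only the student carries the
   regressor, matching the asymmetric design in which the adapter exists
   to lift student features into the teacher's representation space.
2. **Soft-label distillation.** With the tempered softmax
   $p_i(z;T) = \exp(z_i/T)/\sum_j \exp(z_j/T)$, the student matches the
   teacher's smoothed distribution through the cross-entropy
   $L_2 = \tfrac1N \sum_n \sum_i -p_i(z_t^{(n)};T)\log p_i(z_s^{(n)};T)$.
   Larger $T$ makes the teacher distribution smoother, so relatively more
   of the signal describes the *minor* classes.
3. **Focal hard-label loss.**
   $L_3 = \tfrac1N\sum_n -\alpha_{y_n}(1-p_{y_n})^{\gamma}\log p_{y_n}$,
   down-weighting easy examples via $(1-p)^\gamma$ and up-weighting rare
   classes via per-class weights $\alpha_t$.

The total objective is
$$L = \alpha L_1 + (1-\alpha) L_2 + \beta L_3 .$$

The reference protocol fixes $\alpha = 0.5$, $\beta = 1$. We read its
"three training stages" as the three components of this single jointly
optimized objective rather than three sequential phases, because the
combined loss above is stated as *the* training objective; a configurable
feature-matching-only warm-up (`warmupEpochs`, default 0) accommodates the
sequential reading for users who want it.

### Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `alpha` | 0.5 | balance of feature vs soft-label terms (reference value) |
| `beta` | 1 | weight of the focal term (reference value) |
| `temperature` | 4 | softmax temperature; the reference protocol states none, 4 is the conventional distillation choice |
| `gamma` | 2 | focal exponent; unstated in the reference, 2 is the standard value |
| `classWeights` | inverse frequency, mean 1 | $\alpha_t \propto 1/n_t$, normalized so the average weight is 1; `classWeights()` |
| `learningRate` | 0.001 | AdamW step size (reference protocol) |
| `weightDecay` | 5e-4 | decoupled decay, applied to weights but not biases |
| `momentumBeta1` | 0.9 | AdamW first-moment decay; the protocol's "momentum 0.9" is read this way since AdamW has no classical momentum |
| `epochs`, `batchSize` | 100, 32 | reference protocol |
| `nRepeats` | 5 | independent re-split + retrain repeats, seeds seed+0..4 |

No `T^2` rescaling is applied to $L_2$ by default — the combined loss is
implemented exactly as written; `tsquare = TRUE` enables the classic
correction that keeps soft-label gradient magnitudes comparable across
temperatures.

### Training modes

`plain` optimizes $L_3$ only (no teacher); `logits` adds $(1-\alpha)L_2$;
`feature` adds $\alpha L_1$; `full` uses all three terms. All modes log
the three components per epoch, with absent terms recorded as zero, so
`total` always equals $\alpha L_1 + (1-\alpha)L_2 + \beta L_3$ — this
decomposition is asserted in the tests at 1e-6. In every distillation mode
the teacher runs in inference mode and its parameters are never registered
with the optimizer; the tests check bitwise that training leaves them
untouched. A `freezeAllButHead` flag restricts optimization to the
classification head for the pure transfer-learning baseline; it defaults
to off in distillation modes because feature matching is vacuous when the
trunk cannot move.

## Backbones and partitioning

The staged-backbone contract is structural, not architectural: any network
expressible as an ordered list of blocks cut at four boundaries, with a
head, qualifies (`partitionBackbone()` checks that the boundaries are four,
known, strictly increasing, and exhaust the trunk). The composed staged
forward is the same sequence of operations as the flat forward, so the two
agree bitwise — an invariant the tests assert rather than assume.

The bundled `miniatureBackbone()` is a small ConvNeXt-like staged CNN
(patchify 4×4/stride-4 stem, then stride-2 downsampling plus stride-1
mixing convolutions, ReLU activations, global-average-pool + linear head,
~7×10⁴ parameters at default widths) with the same 4/8/16/32 schedule as
the full-size reference backbones. It exists so the entire training
framework is exercisable on one CPU in minutes; it makes no claim to
reproduce full-backbone accuracy. Convolutions and their adjoints are
evaluated as strided-slice matrix products (BLAS GEMM), and every analytic
gradient — losses and network — is validated against central finite
differences in the test suite.

Because both default backbones share the downsampling schedule,
corresponding stages have equal spatial sizes and the feature-matching loss
reduces to channel projection + MSE. If a plugged backbone pair disagrees
spatially at some stage, the adapted student map is bilinearly resized
(half-pixel alignment) to the teacher's size; the resize is implemented as
an explicit linear operator so its exact adjoint is available to the
gradient.

## Data pipeline

**Splitting.** `splitDataset()` is stratified per class and deterministic
given its seed. The training share is `round(0.8 * n_c)` — the rounding
rule that reproduces the reference cohort's published per-class training
counts (total 1,778 of 2,221). The cohort's validation/test remainders
follow no per-class arithmetic rule (its split was drawn at lesion level),
so the held-out assignment is a package design choice: validation receives
`floor(q * n_c)` with `valFraction` q = 0.1065, the interior of the
interval on which the cohort's published validation/test totals (234/209)
are reproduced, and test takes the rest. A class of 10 still splits
exactly 8/1/1. Every nonempty class contributes at least one training
sample. A pooled (non-stratified) mode and a group-by-lesion mode (all
images of a lesion stay in one split, preventing leakage) are available.

**Augmentation** (training split only): horizontal/vertical flips, random
crop removing at most 10% of the area, random translation up to 10% per
axis, edge-padded — the reference recipe's caps are enforced by the
configuration's validity checks. Validation and test see preprocessing
only. At desk scale augmentation operates on the preprocessed tensors,
which is equivalent here because the synthetic images are generated at the
model's input size.

**Input geometry.** Default input is 3-channel RGB. The reference text
mentions a 224×224×1 input, but the source photographs are colour; we read
the ×1 as a slip and default to ×3, keeping a grayscale mode
(`channels = 1`, luminance conversion) for the literal reading.

**Class weights.** `classWeights()` returns inverse-frequency weights
normalized to mean 1 (so `w_c * n_c` is constant across classes); they are
the default focal $\alpha_t$.

## The synthetic task

The clinical dataset behind the reference results is not publicly
available, so the package ships a generator of histology-like synthetic
images: per class a background hue with a mild vertical gradient,
elliptical "cell-cluster" blobs, thin line structures, and Gaussian pixel
noise, written as PNGs in class subfolders, byte-identical for a given
seed. Defaults emulate the statistical structure the method needs and
nothing more: 5 classes in the cohort's 41:1317:196:121:546 proportions
(largest-remainder apportionment; 300 images at 64×64 by default, giving
per-class counts 6/178/26/16/74), severe minority classes included. A
`difficulty` knob interpolates all per-class appearance parameters
linearly toward their mean: at 1 the classes are indistinguishable by
construction, and `expectedSeparability()` — the normalized mean pairwise
distance between standardized class parameter vectors — decreases exactly
as $1-d$.

What passing tests on this fixture do and do not show: they demonstrate
that the losses, gradients, partitioning, freezing, splitting and
evaluation machinery behave exactly as specified, and that on a learnable
imbalanced task the full distillation objective does not hurt the student.
They do not demonstrate clinical-grade accuracy, robustness to staining or
acquisition variation, or the magnitude of distillation gains on real
histopathology — synthetic classes are separable mainly by colour and
simple texture, which is far easier than real tissue morphology.

## Desk-scale study sizes

The bundled study (tests and the acceptance script) uses 300 synthetic
images at 64×64 with the cohort proportions, miniature
teacher (stage widths 12/24/48/96) and student (8/16/32/64), 20 training
epochs, batch 32, and the reference optimizer settings; the ablation
compares the four modes over 5 seeds (fresh split and initialization per
seed, teacher retrained per seed in plain mode), and the learnability
check trains the plain student over 3 seeds at difficulty 0, where it
should master the task (macro-F1 ≥ 0.8). These sizes are the package's
choice of a configuration small enough to run routinely yet large enough
for the qualitative ordering (full KD vs plain) to be examined; at this
scale that ordering is a stochastic property of means over seeds, not a
per-seed guarantee.

Two desk-scale caveats deserve emphasis. First, at difficulty 0.3 the
synthetic classes remain largely colour-separable, so the *plain* student
already attains macro-F1 of 1.0 on most seeds — a ceiling that leaves
distillation no headroom to demonstrate a gain, unlike the clinical
setting where the baseline has ample room for improvement. Second, with
the cohort's proportions at 300 images the rarest class contributes a
single test image (and no validation image), so per-seed macro-F1 moves
in steps of roughly 0.2 with that one prediction, and best-on-validation
checkpoint selection cannot see the rarest class at all. Mode comparisons
at this scale are therefore dominated by discreteness noise; the per-mode
means are reported for inspection rather than as evidence of effect
sizes.

## Numerical choices and edge cases

- Tempered softmax subtracts the row maximum before exponentiation.
- The focal loss clamps $p_y$ at 1e-12 before the logarithm, so a
  confidently wrong prediction yields a large finite loss, not $-\infty$.
- Prediction ties break toward the lowest class index, making evaluation
  deterministic.
- Precision for a class that received no predictions is reported as 0 and
  flagged (`nUndefined`) rather than NaN, keeping macro averages defined
  on small test splits.
- Two macro-F1 variants are reported: the mean of per-class F1
  (`macroF1`) and the harmonic mean of macro precision and macro recall
  (`macroF1Paper`). The reference ablation table's F1 column is
  reproducible from its printed precision/recall columns only under the
  second reading, hence the name; both are always computed.
- Confusion matrices are stored rows = true, columns = predicted (the
  dominant ecosystem convention); `printTransposed()` offers the
  transposed display some reports use.
- AdamW uses $\beta_2 = 0.999$, $\epsilon = 10^{-8}$, bias-corrected
  moments, and applies decay only to weight matrices, never biases.
- Adapters and convolutions initialize He-normal, deterministically from
  the seed; `buildAdapters()` creates learnable adapters even when
  student and teacher channel counts coincide.
- Best-on-validation selection keeps the checkpoint with the highest
  validation *accuracy* seen so far (earliest epoch wins ties).

## Known limitations

- The miniature backbones are stand-ins: absolute accuracies on the
  synthetic task say nothing about full-size backbones on real data.
- The soft-label loss without `tsquare` makes the effective weight of
  $L_2$ shrink as $T$ grows; users sweeping temperatures should enable
  the rescaling for comparability.
- Lesion-aware splitting requires a `lesion_id` column; without it the
  split is image-level and cross-split lesion leakage is possible on real
  clinical data.
- Training is single-threaded CPU R; it is intended for method validation
  and desk-scale experiments, not production training of large backbones.
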