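---
title: "Multi-scale U-Net blocks: model, design decisions, and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale U-Net blocks: model, design decisions, and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A standard U-Net extracts features at every resolution level with one
double-convolution block of a fixed kernel size (3×3), so every level sees a
single receptive field. The multi-scale block generalizes this: several
*branches*, each a sequence of two stacked convolutions with its own kernel
size $k \in \{1, 2, 3, 5, 7, 9\}$, are applied in parallel to the *same*
input $x$ (weights are not shared between branches). For the two-branch
block with kernels 3 and 7,

$$x_1 = W_{3,2}\,\sigma(W_{3,1} x + b_{3,1}) + b_{3,2}, \qquad
  x_2 = W_{7,2}\,\sigma(W_{7,1} x + b_{7,1}) + b_{7,2},$$

the branch outputs are fused by channel concatenation
$X = [\,x_1, x_2\,]$ (or, as a variant, elementwise summation), and a 1×1
convolution reduces the fused map back to the block width:

$$F = W_f X + b_f.$$

Every enumerated block contains the 3×3 branch; combining it with each
non-empty subset of the remaining five kernel types yields the family of
$2^5 - 1 = 31$ parallel blocks, named by their sorted digit strings
(`"13"`, `"37"`, …, `"123579"`). `enumerate_block_configs()` produces
exactly this family. Beyond the parallel family the package builds:

* **Sum fusion** (`"37+sum"`): branch outputs are added instead of
  concatenated, then reduced by the same 1×1 convolution.
* **Serial arrangements** (`"37+concatenated"`, `"73+concatenated"`): the
  two two-convolution stages are applied in sequence, with no parallel
  split and no fusion convolution; the two orders are distinct
  parameterizations of the same shape contract.
* **Dilated substitution** (`"37+dilated"`): the 7×7 branch is replaced by
  a 3×3 kernel at dilation 3. The effective receptive width
  $d(k-1)+1 = 7$ is preserved while the parameter count strictly drops.
* **Residual variants**: `res1` concatenates the block input with the
  branch outputs before the fusion convolution,
  $X_R = [\,x, x_1, x_2\,]$, so the fusion input width is
  $c_\mathrm{in} + 2\,c_\mathrm{out}$; `res0` adds the input to the fused
  output through an identity (or, when the widths differ, a bias-free 1×1
  projection).

Replacing the plain blocks of a U-shaped encoder–decoder with any of these
blocks — on both paths, the contraction path only, or the expansion path
only — gives the architecture family exposed through
`build_architecture()`: the multi-scale U-Net and its placement variants,
the residual versions, an attention-gated variant (additive attention gates
on the skip connections), and a nested dense-skip variant in which every
node of the triangular node grid is the configured block. A
parameter-matched **wide U-Net** control is solved by
`build_wide_unet()`.

## Design decisions

The following choices were genuinely open (the block definitions above fix
the topology but not the micro-architecture); each is exposed as a
configuration switch where that is useful.

**Per-convolution micro-architecture.** Every convolution — including the
1×1 fusion convolution — is followed by batch normalization and ReLU. This
is the prevailing convention of the U-Net-variant literature; setting
`batchnorm = FALSE` gives the original-U-Net conv+ReLU style. Convolutions
keep bias terms in both modes (a bias feeding a batch-norm layer is
mathematically redundant — its gradient is exactly zero — but retaining it
keeps the two modes structurally identical).

**Branch widths.** Each parallel branch outputs the full block width
$c_\mathrm{out}$, so concatenation fusion sees $k \cdot c_\mathrm{out}$
channels before the 1×1 reduction. This follows the dimensional logic of
the fusion equations above.

**Same-padding, including the even 2×2 kernel.** All convolutions use
stride 1 with same-padding so that the spatial shape contract holds for
every kernel in the family. For the even 2×2 kernel, whose total padding
(1) cannot be split symmetrically, the extra pixel is padded on the
top/left.

**Residual block (0) wiring.** Only the concatenating variant is defined
algebraically; for the additive variant we chose a skip around the *whole*
fused block, applied after the fusion stage's activation:
$F_R = \mathrm{block}(x) + \mathrm{proj}(x)$. This makes the block an
exact identity when the block path is zero-initialized — the canonical
residual property, and the one the test suite asserts bitwise.

**Upsampling and skip order.** The decoder upsamples with 2×2 transposed
convolutions by default (bilinear interpolation is selectable); the
decoder block consumes `[skip, upsampled]` in that fixed order. The
attention-gated variant gates each skip with the coarser pre-upsampling
decoder feature: both inputs are projected by 1×1 convolutions to
$\max(1, c_s/2)$ channels (the skip after stride-2 subsampling), summed,
passed through ReLU, reduced to one channel, squashed by a sigmoid and
upsampled (nearest) back to the skip resolution.

**Contraction path.** The bottleneck block is treated as part of the
contraction path, so the `encoder_only` placement replaces it along with
the encoder blocks.

**Initialization.** He-normal (fan-in) for convolution weights, zeros for
biases, unit gain / zero offset for batch norm. Building a network with a
`seed` makes initialization bitwise reproducible.

**Output head.** A 1×1 convolution produces one logit per pixel; the
network output is its sigmoid, a foreground probability in $[0, 1]$. All
emulated tasks are binary; multi-class heads are out of scope.

## Evaluation measures

With pooled pixel tallies TP, FP, FN, TN:

$$\mathrm{IoU} = \frac{TP}{TP+FP+FN}, \qquad
  \mathrm{Dice} = \frac{2\,TP}{2\,TP+FP+FN}, \qquad
  \mathrm{Precision} = \frac{TP}{TP+FP},$$

with the convention that a metric whose denominator vanishes is 1 when
prediction and truth are both empty and 0 otherwise (the standard
benchmark convention for degenerate images). Dice and IoU are linked by
$\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$, which the tests assert
on random confusion tables. Counts are pooled over all pixels of the
evaluated set (micro-average) at binarization threshold 0.5; both are
arguments of `evaluate()`.

AUC is computed by trapezoidal integration of the ROC curve over score
thresholds with midrank handling of ties, which makes it equal to the
Mann–Whitney pairwise-comparison fraction; the tests verify that equality
against a brute-force pairwise oracle and against an established ROC
implementation.

Per-fold values are aggregated as mean ± sample standard deviation
($n-1$ denominator; 0 for a single fold). Pairwise comparison of fold
values uses the classical *pooled-variance* two-sample t test with a
two-sided p-value (delegated to `stats::t.test(var.equal = TRUE)`); we
chose the pooled form because the compared samples are five-fold results
of equal size and provenance, where the equal-variance assumption is
natural.

## Synthetic data and the split protocol

`synthesize_dataset()` emulates the *shape* of four binary-segmentation
modalities, not their physics:

* **blobs** — one to three random ellipses, darker than the background
  with multiplicative speckle (factor 0.25) and additive Gaussian noise
  (σ = 0.03): an ultrasound/dermoscopy lesion analogue. Foreground =
  lesion.
* **membranes** — a random tessellation; pixels near the ridge between
  the two nearest generators are dark boundaries, the rest are bright
  interiors. Foreground = cell interiors, background = membranes,
  matching the electron-microscopy ground-truth convention.
* **bilobe** — two large smooth lateral regions darker than the
  surround: a chest-radiograph lung-field analogue.
* **nuclei** — many small dark blobs on a light, lightly tinted RGB
  background: a stained-histology analogue.

Images are generated on the pixel grid (row-major, origin top-left),
blurred, noised, clipped to $[0,1]$ and quantized to the 8-bit grid, so a
disk round-trip (PNG or TIFF, masks stored as {0, 255}) is lossless.
Noise levels and object-count ranges were fixed once at values that make
the tasks visually plausible and non-trivially learnable; they are style
parameters, not tuning knobs. What the generator deliberately does *not*
reproduce: anatomical texture, intensity calibration, annotation noise,
class imbalance across images, and acquisition artifacts. A model ranking
obtained on these fixtures therefore demonstrates that the pipeline
learns and evaluates correctly — not that one architecture would win on
real clinical data.

`make_splits()` implements the evaluation protocol: the images are
randomly divided into six near-equal subsets; one subset (the sixth by
default — the protocol only requires *a* held-out subset, so the choice
is exposed) is the test set, and five-fold cross-validation over the
remaining pool alternates training and validation at a fixed 4:1 ratio,
the five validation sets partitioning the pool.

## Training

SGD with learning rate $10^{-2}$ and momentum 0.9, no weight decay and no
schedule. The loss is binary cross-entropy on the logits by default
(numerically stable form); soft-Dice and BCE+Dice are selectable — the
loss, epoch budget and batch size are configuration, not constants.
Within each fold the best-validation-IoU checkpoint is kept (model
selection by validation IoU). Training is deterministic under a fixed
config seed: the same seed reproduces the minibatch order, the loss
trace, and the final parameters bitwise.

Batch-norm layers use batch statistics during training and exponential
running averages (momentum 0.1, ε = 10⁻⁵) at evaluation time.
A non-finite loss aborts training with a diagnostic rather than
continuing on a diverged model.

## The desk-scale benchmark

`run_smoke_benchmark()` is the package's standard end-to-end check at
sizes chosen to exercise the full pipeline on a single CPU: MSU-Net(37)
at base width 16 and 4 levels (≈2.9 M parameters) trained on 120 blob
images at 64×64 for 15 epochs on one cross-validation fold, then scored
on the held-out test subset against the untrained initial network. One
fold suffices here because the benchmark asks whether the pipeline
learns, not for a cross-validated mean; `train()` accepts any subset of
folds when the full five-fold protocol is wanted. Under the default seed
the trained test IoU is far above both the 0.70 bar and the untrained
baseline. `run_ablation()` runs the same loop over any set of registry
names (including the full 31-block family via `"all31"`), is resumable,
and reports mean ± SD with the best row flagged.

## Numerical notes and limitations

* Same-padding keeps spatial dims for all kernels and dilations; inputs
  to U-shaped networks must be divisible by $2^{L-1}$ for $L$ levels.
* Max-pooling breaks ties toward the first element in top-left-first
  order; its backward routes the gradient to the stored argmax.
* The engine is dense double-precision CPU code (im2col + BLAS GEMM
  kernels); there is no GPU path, so training at the original U-Net
  widths (base 64, five levels, 512×512 images) is outside the intended
  problem sizes. The toolkit's purpose is architecture construction,
  desk-scale ablation and protocol-faithful evaluation.
* 3D segmentation, multi-class heads, learned fusion, depthwise
  variants, and pretrained encoders are out of scope.
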