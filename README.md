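# msunet

Multi-scale U-Net building blocks, segmentation architectures, and a
cross-validated evaluation harness for 2D binary segmentation, in pure
R + Rcpp.

## The problem

U-shaped encoder–decoder networks dominate biomedical image segmentation
(cell membranes in electron microscopy, breast lesions in ultrasound,
lung fields in chest radiographs, skin lesions, stained nuclei), but the
classic design extracts features at every scale with a single fixed
receptive field — one 3×3 double-convolution block per level. Features
become redundant when the receptive field is too small for the target and
small structures are missed when it is too large.

The **multi-scale block** addresses this by running several
two-convolution branches with *different* kernel sizes
(k ∈ {1, 2, 3, 5, 7, 9}) in parallel over the same input and fusing them:

    x₁ = W₃₂ σ(W₃₁ x + b₃₁) + b₃₂        (3×3 branch)
    x₂ = W₇₂ σ(W₇₁ x + b₇₁) + b₇₂        (7×7 branch)
    X  = Cat[x₁, x₂]                      (concatenation fusion)
    F  = W_f X + b_f                      (1×1 reduction)

Combining the mandatory 3×3 branch with every non-empty subset of the
other five kernel types yields a family of 2⁵ − 1 = 31 blocks, named by
their digit strings ("13" … "123579"). The package builds this whole
family plus its variants — sum fusion, serial (concatenated)
arrangements, a dilated substitution that preserves the 7-pixel receptive
width at lower parameter cost, and two residual wirings — and drops any
of them into:

* a U-shaped network (both paths, encoder-only, or decoder-only),
* an attention-gated U-Net (additive skip gates),
* a nested dense-skip network (U-Net++-style triangular node grid),
* plus a parameter-matched **wide U-Net** control solved by bisection.

Evaluation follows the standard cross-validated protocol: a six-subset
split with one held-out test subset, five-fold cross-validation at a 4:1
train:validation ratio, pixel-pooled IoU / Dice / precision, trapezoidal
ROC/AUC, mean ± SD over folds, and pooled-variance two-sample t tests
between architectures. Because real clinical datasets cannot ship with a
package, a seedable synthetic generator emulates the *shape* of four
modalities (lesion blobs, membrane tessellations, paired lung-like
lobes, dense nuclei) so the entire pipeline — generate, split, train,
select, evaluate, compare — runs end-to-end on a single CPU.

Everything runs on a self-contained double-precision CPU engine
(im2col + BLAS convolutions, batch normalization, max-pooling,
transposed convolutions, SGD with momentum) compiled via
Rcpp/RcppArmadillo; no external deep-learning runtime is required.

## Worked example

```r
library(msunet)

# the 31-block family
cfgs <- enumerate_block_configs()
length(cfgs)
#> [1] 31
cfgs[["37"]]
#> multi-scale block "37": parallel, concat fusion, residual none, 64 -> 64 channels
#>   kernels: 3, 7

# a multi-scale U-Net and its parameter-matched wide control
msu  <- build_architecture("msunet", levels = 4, base_width = 16, seed = 1)
msu
#> segmentation network: 4 levels, widths 16/32/64/128, block 37, skips plain
#>   placement both, upsampling transposed_conv, 2924737 trainable parameters
wide <- build_wide_unet(msu, tolerance = 0.10, seed = 2)
abs(n_parameters(wide$net) - n_parameters(msu$net)) / n_parameters(msu$net)
#> [1] 0.0005545798

# synthetic lesions, the six-subset / five-fold protocol, training
data   <- synthesize_dataset(synthetic_style("blobs", image_size = 64), 30, seed = 1)
splits <- make_splits(30, seed = 1)
splits
#> split plan: n=30, six subsets (sizes 5/5/5/5/5/5), test subset 6 (5 images)
#>   fold 1: 20 train / 5 val
#>   ...
net <- build_architecture("msunet", levels = 3, base_width = 8,
                          in_channels = 1, seed = 1)
tr  <- train(net, splits, data, train_config(epochs = 4, seed = 1), folds = 1)
ev  <- evaluate(tr$networks[[1]], data, splits$test)
c(iou = ev$iou, dice = ev$dice, auc = ev$auc)
#>       iou      dice       auc
#> 0.7560491 0.8610797 0.9590899
```

`evaluate()` reports pixel-pooled overlap between thresholded
probability maps and ground truth on the held-out subset: here the
trained network recovers ~76% IoU (≈0.86 Dice) on unseen lesions after
just four epochs at toy width, with AUC near 1 showing the raw probabilities rank
foreground above background almost perfectly. `run_ablation()` repeats
this loop over any set of architectures (e.g. `"all31"`) on identical
data and seeds, and `compare()` attaches t-test p-values to any pair of
per-fold results.

A thin command-line front end with `synthesize`, `train`, `evaluate`,
`ablate` and `compare` subcommands lives at `inst/cli/msunet.R`.

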