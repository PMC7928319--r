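# Multi-scale convolution blocks.
#
# A multi-scale block runs several two-convolution sequences ("branches")
# with different kernel sizes over the same input, fuses the branch outputs
# (channel concatenation or elementwise sum) and reduces the fused map with
# a 1x1 convolution. Residual variants add or concatenate the block input.

KERNEL_SIZES <- c(1L, 2L, 3L, 5L, 7L, 9L)
CONVS_PER_BRANCH <- 2L

#' Kernel specification
#'
#' @param size kernel side length; one of 1, 2, 3, 5, 7, 9
#' @param dilation dilation rate (1 = dense convolution)
#' @return a `kernel_spec` object
#' @export
kernel_spec <- function(size, dilation = 1L) {
  size <- as.integer(size); dilation <- as.integer(dilation)
  if (!(size %in% KERNEL_SIZES))
    stop("kernel size must be one of {", paste(KERNEL_SIZES, collapse = ","),
         "}, got ", size)
  if (dilation < 1L) stop("dilation must be >= 1")
  structure(list(size = size, dilation = dilation), class = "kernel_spec")
}

as_kernel_spec <- function(k) {
  if (inherits(k, "kernel_spec")) return(k)
  if (is.numeric(k) && length(k) == 1L) return(kernel_spec(k))
  stop("cannot interpret kernel spec")
}

#' @export
format.kernel_spec <- function(x, ...) {
  if (x$dilation == 1L) sprintf("%d", x$size)
  else sprintf("%d(d%d)", x$size, x$dilation)
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("kernel %dx%d, dilation %d (receptive width %d)\n",
              x$size, x$size, x$dilation,
              receptive_width(x$size, x$dilation)))
  invisible(x)
}

#' Multi-scale block configuration
#'
#' Describes one block variant: the kernel set of its parallel (or serial)
#' branches, the fusion rule, and the residual wiring.
#'
#' @param kernels list of [kernel_spec()] objects, or a numeric vector of
#'   kernel sizes (e.g. `c(3, 7)` for the "37" block)
#' @param in_channels,out_channels channel widths of the block
#' @param fusion `"concat"` (channel concatenation, the default) or `"sum"`
#'   (elementwise sum); both are followed by the 1x1 reduction convolution
#' @param topology `"parallel"` (all branches see the same input) or
#'   `"serial"` (exactly two kernel stages applied in sequence, no fusion
#'   convolution)
#' @param residual `"none"`, `"additive_0"` (input added to the fused
#'   output, through a 1x1 projection when widths differ) or `"concat_1"`
#'   (input concatenated with the branch outputs before the fusion
#'   convolution)
#' @param batchnorm logical; insert batch normalization after every
#'   convolution (`FALSE` gives the original-U-Net conv+ReLU style)
#' @param bias logical; convolutions carry bias terms
#' @param name optional display name; defaults to the sorted digit string
#' @return an `ms_block_config` object
#' @export
ms_block_config <- function(kernels, in_channels, out_channels,
                            fusion = c("concat", "sum"),
                            topology = c("parallel", "serial"),
                            residual = c("none", "additive_0", "concat_1"),
                            batchnorm = TRUE, bias = TRUE, name = NULL) {
  fusion <- match.arg(fusion)
  topology <- match.arg(topology)
  residual <- match.arg(residual)
  if (is.numeric(kernels)) kernels <- lapply(kernels, kernel_spec)
  kernels <- lapply(kernels, as_kernel_spec)
  if (length(kernels) == 0L) stop("kernels must be non-empty")
  if (topology == "serial" && length(kernels) != 2L)
    stop("serial topology is defined for exactly two kernel specs")
  if (residual != "none" && topology != "parallel")
    stop("residual wiring is only defined for parallel topology")
  in_channels <- as.integer(in_channels)
  out_channels <- as.integer(out_channels)
  if (in_channels < 1L || out_channels < 1L) stop("channel widths must be >= 1")
  if (is.null(name)) {
    digits <- vapply(kernels, function(k) k$size, integer(1))
    if (topology == "parallel") digits <- sort(digits)
    name <- paste(digits, collapse = "")
  }
  structure(list(kernels = kernels, fusion = fusion, topology = topology,
                 residual = residual, in_channels = in_channels,
                 out_channels = out_channels,
                 convs_per_branch = CONVS_PER_BRANCH,
                 batchnorm = isTRUE(batchnorm), bias = isTRUE(bias),
                 name = name),
            class = "ms_block_config")
}

#' @export
print.ms_block_config <- function(x, ...) {
  cat(sprintf("multi-scale block \"%s\": %s, %s fusion, residual %s, %d -> %d channels\n",
              x$name, x$topology, x$fusion, x$residual,
              x$in_channels, x$out_channels))
  cat("  kernels:", paste(vapply(x$kernels, format, character(1)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate the parallel multi-scale block family
#'
#' The family combines the 3x3 branch with every non-empty subset of the
#' remaining kernel types \{1, 2, 5, 7, 9\}, giving 31 configurations named
#' by their sorted digit strings ("13", "37", ..., "123579"). All use
#' concatenation fusion and no residual wiring.
#'
#' @param in_channels,out_channels channel widths applied to every
#'   configuration
#' @param batchnorm see [ms_block_config()]
#' @return named list of 31 `ms_block_config` objects
#' @export
enumerate_block_configs <- function(in_channels = 64L, out_channels = 64L,
                                    batchnorm = TRUE) {
  others <- setdiff(KERNEL_SIZES, 3L)
  configs <- list()
  for (sz in seq_along(others)) {
    combos <- utils::combn(others, sz, simplify = FALSE)
    for (cmb in combos) {
      ks <- sort(c(3L, cmb))
      cfg <- ms_block_config(ks, in_channels, out_channels,
                             batchnorm = batchnorm)
      configs[[cfg$name]] <- cfg
    }
  }
  configs[order(nchar(names(configs)), names(configs))]
}

#' Build one convolution branch
#'
#' A branch is two stacked convolutions of the same kernel (the first maps
#' `in_channels` to `out_channels`, the second preserves `out_channels`),
#' each followed by batch normalization (optional) and ReLU, with
#' same-padding so spatial dims are preserved.
#'
#' @param kernel a [kernel_spec()] or a single kernel size
#' @param in_channels,out_channels channel widths
#' @param batchnorm,bias micro-architecture switches
#' @return a module; run it with [nn_forward()]
#' @export
build_conv_branch <- function(kernel, in_channels, out_channels,
                              batchnorm = TRUE, bias = TRUE) {
  kernel <- as_kernel_spec(kernel)
  unit <- function(cin, cout) {
    layers <- list(conv_layer(kernel$size, cin, cout,
                              dilation = kernel$dilation, bias = bias))
    if (batchnorm) layers <- c(layers, list(bn_layer(cout)))
    c(layers, list(relu_layer()))
  }
  nn_sequential(c(unit(in_channels, out_channels),
                  unit(out_channels, out_channels)))
}

# 1x1 fusion/head unit: conv (+ BN) + ReLU
fusion_unit <- function(in_channels, out_channels, batchnorm, bias) {
  layers <- list(conv_layer(1L, in_channels, out_channels, bias = bias))
  if (batchnorm) layers <- c(layers, list(bn_layer(out_channels)))
  nn_sequential(c(layers, list(relu_layer())))
}

#' Build a multi-scale block from its configuration
#'
#' Dispatches on the topology: parallel configurations get independent
#' branches plus the 1x1 fusion convolution (and residual wiring if
#' configured); serial configurations get the two kernel stages in
#' sequence with no fusion convolution.
#'
#' @param cfg an [ms_block_config()]
#' @return a module
#' @export
build_block <- function(cfg) {
  stopifnot(inherits(cfg, "ms_block_config"))
  if (cfg$topology == "serial") return(build_serial_block(cfg))
  build_ms_block(cfg)
}

build_ms_block <- function(cfg) {
  branches <- lapply(cfg$kernels, function(k)
    build_conv_branch(k, cfg$in_channels, cfg$out_channels,
                      batchnorm = cfg$batchnorm, bias = cfg$bias))
  nb <- length(branches)
  fin <- switch(cfg$fusion,
                concat = nb * cfg$out_channels,
                sum = cfg$out_channels)
  if (cfg$residual == "concat_1") {
    if (cfg$fusion != "concat")
      stop("residual concat wiring requires concatenation fusion")
    fin <- fin + cfg$in_channels
  }
  fusion <- fusion_unit(fin, cfg$out_channels, cfg$batchnorm, cfg$bias)
  proj <- NULL
  if (cfg$residual == "additive_0" && cfg$in_channels != cfg$out_channels)
    proj <- conv_layer(1L, cfg$in_channels, cfg$out_channels, bias = FALSE)
  new_module("ms_block", cfg = cfg, branches = branches,
             fusion = fusion, proj = proj)
}

#' @export
nn_forward.ms_block <- function(m, x, training = TRUE) {
  cfg <- m$cfg
  if (dim(x)[3] != cfg$in_channels)
    stop("input has ", dim(x)[3], " channels but block expects ",
         cfg$in_channels)
  outs <- lapply(m$branches, nn_forward, x = x, training = training)
  if (cfg$fusion == "sum") {
    X <- Reduce(`+`, outs)
  } else if (cfg$residual == "concat_1") {
    X <- concat_channels(c(list(x), outs))
  } else {
    X <- concat_channels(outs)
  }
  f <- nn_forward(m$fusion, X, training)
  if (cfg$residual == "additive_0") {
    sk <- if (is.null(m$proj)) x else nn_forward(m$proj, x, training)
    f <- f + sk
  }
  f
}

#' @export
nn_backward.ms_block <- function(m, gy) {
  cfg <- m$cfg
  gskip <- NULL
  if (cfg$residual == "additive_0") {
    gskip <- if (is.null(m$proj)) gy else nn_backward(m$proj, gy)
  }
  gX <- nn_backward(m$fusion, gy)
  nb <- length(m$branches)
  if (cfg$fusion == "sum") {
    gbr <- rep(list(gX), nb)
  } else if (cfg$residual == "concat_1") {
    parts <- split_channels(gX, c(cfg$in_channels, rep(cfg$out_channels, nb)))
    gskip2 <- parts[[1]]
    gskip <- if (is.null(gskip)) gskip2 else gskip + gskip2
    gbr <- parts[-1]
  } else {
    gbr <- split_channels(gX, rep(cfg$out_channels, nb))
  }
  gx <- NULL
  for (i in seq_len(nb)) {
    g <- nn_backward(m$branches[[i]], gbr[[i]])
    gx <- if (is.null(gx)) g else gx + g
  }
  if (!is.null(gskip)) gx <- gx + gskip
  gx
}

#' @export
nn_layers.ms_block <- function(m) {
  c(do.call(c, lapply(m$branches, nn_layers)),
    nn_layers(m$fusion),
    if (!is.null(m$proj)) nn_layers(m$proj) else list())
}

build_serial_block <- function(cfg) {
  stopifnot(cfg$topology == "serial")
  nn_sequential(list(
    build_conv_branch(cfg$kernels[[1]], cfg$in_channels, cfg$out_channels,
                      batchnorm = cfg$batchnorm, bias = cfg$bias),
    build_conv_branch(cfg$kernels[[2]], cfg$out_channels, cfg$out_channels,
                      batchnorm = cfg$batchnorm, bias = cfg$bias)))
}

#' Parallel multi-scale block forward pass
#'
#' Every branch receives the same input (branches do not share weights);
#' branch outputs are fused (concatenation or sum) and reduced by the 1x1
#' convolution. With residual wiring the input is concatenated before the
#' fusion convolution (`concat_1`) or added to its output (`additive_0`).
#'
#' @param x input array, dim `c(H, W, in_channels, N)`
#' @param block a built block module, or an [ms_block_config()] (the block
#'   is then built on the fly with freshly initialized weights)
#' @param training logical, passed through to [nn_forward()]
#' @return output array, dim `c(H, W, out_channels, N)`
#' @export
multiscale_forward <- function(x, block, training = FALSE) {
  if (inherits(block, "ms_block_config")) {
    if (block$topology != "parallel")
      stop("multiscale_forward expects a parallel block; see serial_forward")
    block <- build_ms_block(block)
  }
  stopifnot(inherits(block, "ms_block"))
  nn_forward(block, x, training)
}

#' Residual multi-scale block forward pass
#'
#' Same contract as [multiscale_forward()] but requires residual wiring
#' (`additive_0` or `concat_1`).
#'
#' @inheritParams multiscale_forward
#' @export
residual_multiscale_forward <- function(x, block, training = FALSE) {
  cfg <- if (inherits(block, "ms_block_config")) block else block$cfg
  if (cfg$residual == "none")
    stop("block has no residual wiring")
  multiscale_forward(x, block, training)
}

#' Serial (concatenated) arrangement forward pass
#'
#' Applies one two-convolution sequence of the first kernel, then one of
#' the second, in series; there is no parallel split and no 1x1 fusion.
#'
#' @param x input array
#' @param order two kernel specs (or sizes), applied in the given order
#' @param in_channels,out_channels channel widths; defaults read from `x`
#' @param block optionally a pre-built serial block module
#' @param training logical
#' @return output array
#' @export
serial_forward <- function(x, order, in_channels = dim(x)[3],
                           out_channels = in_channels, block = NULL,
                           training = FALSE) {
  if (is.null(block)) {
    if (length(order) != 2L) stop("serial order must have exactly 2 kernels")
    cfg <- ms_block_config(order, in_channels, out_channels,
                           topology = "serial")
    block <- build_serial_block(cfg)
  }
  nn_forward(block, x, training)
}

#' Dilated substitution of the (37) block
#'
#' Replaces the 7x7 branch with a 3x3 kernel at dilation 3, preserving the
#' effective receptive width (7) while strictly reducing the parameter
#' count.
#'
#' @param cfg a parallel `ms_block_config` containing a 7x7 branch
#' @return the modified configuration
#' @export
dilated_variant <- function(cfg) {
  stopifnot(inherits(cfg, "ms_block_config"))
  sizes <- vapply(cfg$kernels, function(k) k$size, integer(1))
  i <- which(sizes == 7L & vapply(cfg$kernels, function(k) k$dilation,
                                  integer(1)) == 1L)
  if (length(i) == 0L)
    stop("dilated variant applies to configurations with a 7x7 branch")
  cfg$kernels[[i[1]]] <- kernel_spec(3L, dilation = 3L)
  cfg$name <- paste0(cfg$name, "+dilated")
  cfg
}

#' Count trainable parameters
#'
#' For an `ms_block_config` this is the closed-form tally of convolution
#' weights, biases, and batch-norm affine terms across branches, fusion
#' convolution and residual projection. For a built module it walks the
#' parameter containers (see [n_parameters()]); the two agree for every
#' configuration.
#'
#' @param x an `ms_block_config`, a built module, or a network
#' @return integer count of trainable scalars
#' @export
count_parameters <- function(x) UseMethod("count_parameters")

#' @export
count_parameters.ms_block_config <- function(x) {
  conv_n <- function(k, cin, cout)
    k * k * cin * cout + (if (x$bias) cout else 0L) +
      (if (x$batchnorm) 2L * cout else 0L)
  branch_n <- function(k)
    conv_n(k, x$in_channels, x$out_channels) +
      conv_n(k, x$out_channels, x$out_channels)
  sizes <- vapply(x$kernels, function(k) k$size, integer(1))
  if (x$topology == "serial") {
    # stage 1: in -> out, stage 2: out -> out, both two convs deep
    return(conv_n(sizes[1], x$in_channels, x$out_channels) +
             conv_n(sizes[1], x$out_channels, x$out_channels) +
             conv_n(sizes[2], x$out_channels, x$out_channels) +
             conv_n(sizes[2], x$out_channels, x$out_channels))
  }
  tot <- sum(vapply(sizes, branch_n, numeric(1)))
  fin <- if (x$fusion == "concat") length(sizes) * x$out_channels
         else x$out_channels
  if (x$residual == "concat_1") fin <- fin + x$in_channels
  tot <- tot + conv_n(1L, fin, x$out_channels)
  if (x$residual == "additive_0" && x$in_channels != x$out_channels)
    tot <- tot + x$in_channels * x$out_channels   # bias-free 1x1 projection
  as.integer(tot)
}

#' @export
count_parameters.nn_module <- function(x) n_parameters(x)

#' @export
count_parameters.default <- function(x) {
  if (inherits(x, "segmentation_network")) return(n_parameters(x$net))
  stop("cannot count parameters of this object")
}

#' Block factory by name
#'
#' Resolves the block names used throughout the ablation tables:
#' plain digit strings ("37", "123579", ...), fusion variants
#' ("37+sum"), serial arrangements ("37+concatenated",
#' "73+concatenated"), the dilated substitution ("37+dilated"), and the
#' residual variants ("res0:37", "res1:37").
#'
#' @param name block name string
#' @param in_channels,out_channels channel widths
#' @param batchnorm see [ms_block_config()]
#' @return an `ms_block_config`
#' @export
block_config_from_name <- function(name, in_channels = 64L,
                                   out_channels = 64L, batchnorm = TRUE) {
  digits_to_kernels <- function(s) as.integer(strsplit(s, "")[[1]])
  if (grepl("^res[01]:[0-9]+$", name)) {
    mode <- if (substr(name, 4, 4) == "0") "additive_0" else "concat_1"
    ks <- digits_to_kernels(sub("^res[01]:", "", name))
    return(ms_block_config(ks, in_channels, out_channels,
                           residual = mode, batchnorm = batchnorm,
                           name = name))
  }
  if (grepl("^[0-9]+\\+sum$", name)) {
    ks <- digits_to_kernels(sub("\\+sum$", "", name))
    return(ms_block_config(ks, in_channels, out_channels, fusion = "sum",
                           batchnorm = batchnorm, name = name))
  }
  if (grepl("^[0-9]+\\+concatenated$", name)) {
    ks <- digits_to_kernels(sub("\\+concatenated$", "", name))
    return(ms_block_config(ks, in_channels, out_channels,
                           topology = "serial", batchnorm = batchnorm,
                           name = name))
  }
  if (grepl("^[0-9]+\\+dilated$", name)) {
    base <- sub("\\+dilated$", "", name)
    cfg <- ms_block_config(digits_to_kernels(base), in_channels,
                           out_channels, batchnorm = batchnorm)
    return(dilated_variant(cfg))
  }
  if (grepl("^[0-9]+$", name)) {
    return(ms_block_config(digits_to_kernels(name), in_channels,
                           out_channels, batchnorm = batchnorm))
  }
  stop("unknown block name: ", name)
}
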