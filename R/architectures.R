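# Network assembly: U-shaped encoder-decoder segmentation networks built
# from plain double-3x3 blocks or any multi-scale block variant, plus the
# attention-gated and nested-skip (U-Net++ style) topologies.

#' Network assembly specification
#'
#' @param levels encoder depth (number of resolution levels, >= 2)
#' @param base_width channels at the first level; widths double per level
#' @param width_multiplier positive real scaling every level's width
#'   (rounded to the nearest integer, floored at 1); used to build the
#'   parameter-matched wide U-Net
#' @param block `"plain"` for the original double-3x3 convolution block,
#'   a block name string understood by [block_config_from_name()] (e.g.
#'   `"37"`, `"res0:37"`), or an [ms_block_config()] template whose
#'   channel widths are overridden per level
#' @param placement `"both"`, `"encoder_only"` or `"decoder_only"`: where
#'   multi-scale blocks replace the plain blocks (the bottleneck counts as
#'   part of the contraction path)
#' @param upsampling `"transposed_conv"` (2x2 up-convolution, the default)
#'   or `"bilinear"`
#' @param skip_mode `"plain"`, `"attention_gate"` or `"nested"` (dense
#'   nested skips)
#' @param out_classes output channels (1 = binary foreground probability)
#' @param in_channels input image channels (1 grayscale, 3 RGB)
#' @param batchnorm insert batch normalization after every convolution
#' @return a `network_spec` object
#' @export
network_spec <- function(levels = 5L, base_width = 64L,
                         width_multiplier = 1.0, block = "37",
                         placement = c("both", "encoder_only", "decoder_only"),
                         upsampling = c("transposed_conv", "bilinear"),
                         skip_mode = c("plain", "attention_gate", "nested"),
                         out_classes = 1L, in_channels = 1L,
                         batchnorm = TRUE) {
  placement <- match.arg(placement)
  upsampling <- match.arg(upsampling)
  skip_mode <- match.arg(skip_mode)
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  if (width_multiplier <= 0) stop("width_multiplier must be positive")
  structure(list(levels = levels, base_width = as.integer(base_width),
                 width_multiplier = width_multiplier, block = block,
                 placement = placement, upsampling = upsampling,
                 skip_mode = skip_mode, out_classes = as.integer(out_classes),
                 in_channels = as.integer(in_channels),
                 batchnorm = isTRUE(batchnorm)),
            class = "network_spec")
}

spec_widths <- function(spec) {
  vapply(seq_len(spec$levels), function(l)
    max(1L, as.integer(round(spec$base_width * 2^(l - 1) *
                               spec$width_multiplier))), integer(1))
}

# block config (or "plain") for one position in the network
position_block_cfg <- function(spec, cin, cout, on_encoder) {
  use_ms <- !identical(spec$block, "plain") &&
    switch(spec$placement,
           both = TRUE,
           encoder_only = on_encoder,
           decoder_only = !on_encoder)
  if (!use_ms) return(NULL)
  if (is.character(spec$block))
    return(block_config_from_name(spec$block, cin, cout,
                                  batchnorm = spec$batchnorm))
  cfg <- spec$block
  cfg$in_channels <- as.integer(cin)
  cfg$out_channels <- as.integer(cout)
  cfg$batchnorm <- spec$batchnorm
  cfg
}

build_position_block <- function(spec, cin, cout, on_encoder) {
  cfg <- position_block_cfg(spec, cin, cout, on_encoder)
  if (is.null(cfg))
    build_conv_branch(3L, cin, cout, batchnorm = spec$batchnorm)
  else build_block(cfg)
}

# closed-form parameter tallies mirroring the builders; cross-checked in
# tests against a brute-force walk over built networks
block_cfg_params <- function(spec, cin, cout, on_encoder) {
  cfg <- position_block_cfg(spec, cin, cout, on_encoder)
  if (is.null(cfg)) {
    bn <- if (spec$batchnorm) 2L else 0L
    conv_n <- function(k, ci, co) k * k * ci * co + co + bn * co
    return(conv_n(3L, cin, cout) + conv_n(3L, cout, cout))
  }
  count_parameters(cfg)
}

#' Closed-form parameter count of a network specification
#'
#' @param x a [network_spec()]
#' @export
count_parameters.network_spec <- function(x) {
  w <- spec_widths(x)
  L <- x$levels
  bn <- if (x$batchnorm) 2L else 0L
  tot <- 0
  if (x$skip_mode == "nested") {
    for (i in seq_len(L)) {
      cin <- if (i == 1L) x$in_channels else w[i - 1]
      tot <- tot + block_cfg_params(x, cin, w[i], on_encoder = TRUE)
      if (i < L) for (j in seq_len(L - i)) {
        tot <- tot + block_cfg_params(x, (j + 1L) * w[i], w[i],
                                      on_encoder = FALSE)
        tot <- tot + 4L * w[i + 1] * w[i] + w[i]     # up-conv into node
      }
    }
    return(as.integer(tot + w[1] * x$out_classes + x$out_classes))
  }
  for (l in seq_len(L - 1)) {
    cin <- if (l == 1L) x$in_channels else w[l - 1]
    tot <- tot + block_cfg_params(x, cin, w[l], on_encoder = TRUE)
  }
  tot <- tot + block_cfg_params(x, w[L - 1], w[L], on_encoder = TRUE)
  for (l in seq_len(L - 1)) {
    upc <- if (x$upsampling == "transposed_conv") {
      tot <- tot + 4L * w[l + 1] * w[l] + w[l]
      w[l]
    } else w[l + 1]
    tot <- tot + block_cfg_params(x, w[l] + upc, w[l], on_encoder = FALSE)
    if (x$skip_mode == "attention_gate") {
      fint <- max(1L, w[l] %/% 2L)
      tot <- tot + w[l + 1] * fint + fint +   # gate projection (bias)
        w[l] * fint +                         # skip projection (no bias)
        fint + 1L                             # psi to one channel (bias)
    }
  }
  as.integer(tot + w[1] * x$out_classes + x$out_classes)
}

# ---- attention gate --------------------------------------------------------

build_attention_gate <- function(skip_channels, gate_channels, ratio = 2L,
                                 inter_channels = max(1L, skip_channels %/% 2L)) {
  if (ratio < 1L || bitwAnd(ratio, ratio - 1L) != 0L)
    stop("spatial ratio between gate and skip must be a power of 2")
  new_module("att_gate",
             wg = conv_layer(1L, gate_channels, inter_channels, bias = TRUE),
             wx = conv_layer(1L, skip_channels, inter_channels, bias = FALSE),
             psi = conv_layer(1L, inter_channels, 1L, bias = TRUE),
             ratio = as.integer(ratio))
}

#' @export
nn_layers.att_gate <- function(m) {
  c(nn_layers(m$wg), nn_layers(m$wx), nn_layers(m$psi))
}

att_forward <- function(m, skip, gate, training = TRUE) {
  r <- dim(skip)[1] %/% dim(gate)[1]
  if (dim(skip)[1] != r * dim(gate)[1] || bitwAnd(r, r - 1L) != 0L)
    stop("spatial ratio between gate and skip must be a power of 2")
  H <- dim(skip)[1]; W <- dim(skip)[2]; C <- dim(skip)[3]
  sd <- skip[seq(1, H, by = r), seq(1, W, by = r), , , drop = FALSE]
  a <- nn_forward(m$wg, gate, training) + nn_forward(m$wx, sd, training)
  mask <- a > 0
  h <- a * mask
  p <- nn_forward(m$psi, h, training)
  coef_small <- 1 / (1 + exp(-p))
  coef <- coef_small
  steps <- as.integer(round(log2(r)))
  for (s in seq_len(steps)) coef <- cpp_upsample2_fwd(coef, 0L)
  out <- skip * coef[, , rep(1L, C), , drop = FALSE]
  if (training) {
    m$skip <- skip; m$coef <- coef; m$coef_small <- coef_small
    m$mask <- mask; m$r <- r; m$steps <- steps
  }
  out
}

att_backward <- function(m, gy) {
  C <- dim(m$skip)[3]
  gskip <- gy * m$coef[, , rep(1L, C), , drop = FALSE]
  tmp <- gy * m$skip
  d <- dim(tmp)
  gcoef <- array(0, c(d[1], d[2], 1L, d[4]))
  for (cc in seq_len(C)) gcoef[, , 1L, ] <- gcoef[, , 1L, ] + tmp[, , cc, ]
  for (s in seq_len(m$steps))
    gcoef <- cpp_upsample2_bwd(gcoef, dim(gcoef)[1] %/% 2L,
                               dim(gcoef)[2] %/% 2L, 0L)
  gp <- gcoef * m$coef_small * (1 - m$coef_small)
  gh <- nn_backward(m$psi, gp)
  ga <- gh * m$mask
  ggate <- nn_backward(m$wg, ga)
  gsd <- nn_backward(m$wx, ga)
  H <- dim(m$skip)[1]; W <- dim(m$skip)[2]
  gsc <- array(0, dim(m$skip))
  gsc[seq(1, H, by = m$r), seq(1, W, by = m$r), , ] <- gsd
  m$skip <- NULL; m$coef <- NULL; m$mask <- NULL
  list(gskip = gskip + gsc, ggate = ggate)
}

#' Additive attention gate
#'
#' Multiplies an encoder skip feature by per-pixel attention coefficients
#' in \[0, 1\] computed from a coarser decoder gating signal: 1x1
#' projections of both inputs are summed, passed through ReLU, reduced to
#' one channel, squashed by a sigmoid and upsampled to the skip
#' resolution.
#'
#' @param skip encoder feature array `c(H, W, Cs, N)`
#' @param gate coarser decoder feature `c(H/r, W/r, Cg, N)`, `r` a power
#'   of 2
#' @param module optionally a pre-built gate module (from repeated use);
#'   built fresh from the input shapes when `NULL`
#' @return the gated skip feature, same shape as `skip`
#' @export
attention_gate <- function(skip, gate, module = NULL) {
  if (is.null(module)) {
    r <- dim(skip)[1] %/% dim(gate)[1]
    module <- build_attention_gate(dim(skip)[3], dim(gate)[3], ratio = r)
  }
  att_forward(module, skip, gate, training = FALSE)
}

# ---- U-shaped network ------------------------------------------------------

build_unet_module <- function(spec) {
  w <- spec_widths(spec)
  L <- spec$levels
  enc <- vector("list", L - 1); pools <- vector("list", L - 1)
  ups <- vector("list", L - 1); dec <- vector("list", L - 1)
  gates <- if (spec$skip_mode == "attention_gate") vector("list", L - 1) else NULL
  for (l in seq_len(L - 1)) {
    cin <- if (l == 1L) spec$in_channels else w[l - 1]
    enc[[l]] <- build_position_block(spec, cin, w[l], on_encoder = TRUE)
    pools[[l]] <- maxpool_layer()
  }
  bottom <- build_position_block(spec, w[L - 1], w[L], on_encoder = TRUE)
  upc <- integer(L - 1)
  for (l in seq_len(L - 1)) {
    if (spec$upsampling == "transposed_conv") {
      ups[[l]] <- upconv_layer(w[l + 1], w[l]); upc[l] <- w[l]
    } else {
      ups[[l]] <- upsample_layer("bilinear"); upc[l] <- w[l + 1]
    }
    dec[[l]] <- build_position_block(spec, w[l] + upc[l], w[l],
                                     on_encoder = FALSE)
    if (!is.null(gates))
      gates[[l]] <- build_attention_gate(w[l], w[l + 1], ratio = 2L)
  }
  head <- conv_layer(1L, w[1], spec$out_classes, bias = TRUE)
  new_module("unet", spec = spec, widths = w, upc = upc, enc = enc,
             pools = pools, bottom = bottom, ups = ups, dec = dec,
             gates = gates, head = head)
}

check_input_dims <- function(spec, x) {
  div <- 2^(spec$levels - 1)
  d <- dim(x)
  if (length(d) != 4L)
    stop("input must be a 4-d array c(H, W, C, N)")
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop("input spatial dims (", d[1], "x", d[2],
         ") must be divisible by 2^(levels-1) = ", div)
  if (d[3] != spec$in_channels)
    stop("input has ", d[3], " channels, network expects ", spec$in_channels)
}

#' @export
nn_forward.unet <- function(m, x, training = TRUE) {
  check_input_dims(m$spec, x)
  L <- m$spec$levels
  skips <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    x <- nn_forward(m$enc[[l]], x, training)
    skips[[l]] <- x
    x <- nn_forward(m$pools[[l]], x, training)
  }
  x <- nn_forward(m$bottom, x, training)
  for (l in rev(seq_len(L - 1))) {
    gsig <- x
    u <- nn_forward(m$ups[[l]], x, training)
    sk <- skips[[l]]
    if (!is.null(m$gates))
      sk <- att_forward(m$gates[[l]], sk, gsig, training)
    x <- nn_forward(m$dec[[l]], concat_channels(list(sk, u)), training)
  }
  nn_forward(m$head, x, training)
}

#' @export
nn_backward.unet <- function(m, gy) {
  L <- m$spec$levels
  g <- nn_backward(m$head, gy)
  gskips <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    gcat <- nn_backward(m$dec[[l]], g)
    parts <- split_channels(gcat, c(m$widths[l], m$upc[l]))
    gsk <- parts[[1]]
    g <- nn_backward(m$ups[[l]], parts[[2]])
    if (!is.null(m$gates)) {
      r <- att_backward(m$gates[[l]], gsk)
      gsk <- r$gskip
      g <- g + r$ggate
    }
    gskips[[l]] <- gsk
  }
  g <- nn_backward(m$bottom, g)
  for (l in rev(seq_len(L - 1))) {
    g <- nn_backward(m$pools[[l]], g)
    g <- g + gskips[[l]]
    g <- nn_backward(m$enc[[l]], g)
  }
  g
}

#' @export
nn_layers.unet <- function(m) {
  c(do.call(c, lapply(m$enc, nn_layers)),
    nn_layers(m$bottom),
    do.call(c, lapply(m$ups, nn_layers)),
    do.call(c, lapply(m$dec, nn_layers)),
    if (!is.null(m$gates)) do.call(c, lapply(m$gates, nn_layers)) else list(),
    nn_layers(m$head))
}

# ---- nested dense skips (U-Net++ topology) ---------------------------------

build_unetpp_module <- function(spec) {
  w <- spec_widths(spec)
  L <- spec$levels
  bb <- vector("list", L); pools <- vector("list", L - 1)
  nodes <- vector("list", L); ups <- vector("list", L)
  for (i in seq_len(L)) {
    cin <- if (i == 1L) spec$in_channels else w[i - 1]
    bb[[i]] <- build_position_block(spec, cin, w[i], on_encoder = TRUE)
    if (i < L) {
      pools[[i]] <- maxpool_layer()
      nodes[[i]] <- vector("list", L - i)
      ups[[i]] <- vector("list", L - i)
      for (j in seq_len(L - i)) {
        nodes[[i]][[j]] <- build_position_block(spec, (j + 1L) * w[i], w[i],
                                                on_encoder = FALSE)
        ups[[i]][[j]] <- upconv_layer(w[i + 1], w[i])
      }
    }
  }
  head <- conv_layer(1L, w[1], spec$out_classes, bias = TRUE)
  new_module("unetpp", spec = spec, widths = w, bb = bb, pools = pools,
             nodes = nodes, ups = ups, head = head)
}

#' @export
nn_forward.unetpp <- function(m, x, training = TRUE) {
  check_input_dims(m$spec, x)
  L <- m$spec$levels
  X <- lapply(seq_len(L), function(i) vector("list", L - i + 1L))
  for (i in seq_len(L)) {
    x <- nn_forward(m$bb[[i]], x, training)
    X[[i]][[1]] <- x
    if (i < L) x <- nn_forward(m$pools[[i]], x, training)
  }
  for (j in seq_len(L - 1)) {
    for (i in seq_len(L - j)) {
      u <- nn_forward(m$ups[[i]][[j]], X[[i + 1]][[j]], training)
      inp <- concat_channels(c(X[[i]][seq_len(j)], list(u)))
      X[[i]][[j + 1L]] <- nn_forward(m$nodes[[i]][[j]], inp, training)
    }
  }
  nn_forward(m$head, X[[1]][[L]], training)
}

#' @export
nn_backward.unetpp <- function(m, gy) {
  L <- m$spec$levels
  w <- m$widths
  G <- lapply(seq_len(L), function(i) vector("list", L - i + 1L))
  G[[1]][[L]] <- nn_backward(m$head, gy)
  acc <- function(i, j, g) {
    G[[i]][[j]] <<- if (is.null(G[[i]][[j]])) g else G[[i]][[j]] + g
  }
  for (j in rev(seq_len(L - 1))) {
    for (i in seq_len(L - j)) {
      g <- G[[i]][[j + 1L]]
      gin <- nn_backward(m$nodes[[i]][[j]], g)
      parts <- split_channels(gin, rep(w[i], j + 1L))
      for (jj in seq_len(j)) acc(i, jj, parts[[jj]])
      gup <- nn_backward(m$ups[[i]][[j]], parts[[j + 1L]])
      acc(i + 1L, j, gup)
    }
  }
  g <- NULL
  for (i in rev(seq_len(L))) {
    gi <- G[[i]][[1]]
    if (!is.null(g)) gi <- gi + g
    gpre <- nn_backward(m$bb[[i]], gi)
    g <- if (i > 1L) nn_backward(m$pools[[i - 1L]], gpre) else gpre
  }
  g
}

#' @export
nn_layers.unetpp <- function(m) {
  out <- do.call(c, lapply(m$bb, nn_layers))
  for (i in seq_along(m$nodes)) {
    if (is.null(m$nodes[[i]])) next
    for (j in seq_along(m$nodes[[i]])) {
      out <- c(out, nn_layers(m$nodes[[i]][[j]]), nn_layers(m$ups[[i]][[j]]))
    }
  }
  c(out, nn_layers(m$head))
}

# ---- public constructors ---------------------------------------------------

#' Build a segmentation network from a specification
#'
#' Assembles the U-shaped network: per-level blocks with 2x2 max-pool
#' downsampling on the contraction path, upsampling with skip
#' concatenation on the expansion path, and a 1x1 convolution + sigmoid
#' head producing a per-pixel foreground probability map. With
#' `skip_mode = "nested"` the dense nested-skip topology is built instead
#' (see [build_msunetpp()]).
#'
#' @param spec a [network_spec()]
#' @param seed optional integer; when given, parameter initialization is
#'   made reproducible (same spec + same seed = identical parameters)
#' @return a `segmentation_network`
#' @export
build_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(seed)) set.seed(seed)
  net <- if (spec$skip_mode == "nested") build_unetpp_module(spec)
         else build_unet_module(spec)
  structure(list(spec = spec, net = net), class = "segmentation_network")
}

#' Build a nested-skip (U-Net++ style) segmentation network
#'
#' Node `X[i,j]` consumes the upsampled `X[i+1,j-1]` concatenated with all
#' same-level predecessors `X[i,0..j-1]`; every node is the configured
#' block. Deep supervision is not applied; the head reads the final
#' top-level node.
#'
#' @inheritParams build_network
#' @export
build_msunetpp <- function(spec, seed = NULL) {
  spec$skip_mode <- "nested"
  build_network(spec, seed)
}

#' @export
print.segmentation_network <- function(x, ...) {
  s <- x$spec
  cat(sprintf("segmentation network: %d levels, widths %s, block %s, skips %s\n",
              s$levels, paste(spec_widths(s), collapse = "/"),
              if (is.character(s$block)) s$block else s$block$name,
              s$skip_mode))
  cat(sprintf("  placement %s, upsampling %s, %d trainable parameters\n",
              s$placement, s$upsampling, n_parameters(x$net)))
  invisible(x)
}

#' Forward pass of a segmentation network
#'
#' @param network a `segmentation_network`
#' @param x image batch, dim `c(H, W, C, N)`, spatial dims divisible by
#'   `2^(levels-1)`
#' @param training logical; `FALSE` (default) uses batch-norm running
#'   statistics
#' @return per-pixel foreground probability array `c(H, W, out_classes, N)`
#'   with values in \[0, 1\]
#' @export
network_forward <- function(network, x, training = FALSE) {
  stopifnot(inherits(network, "segmentation_network"))
  logits <- nn_forward(network$net, x, training)
  1 / (1 + exp(-logits))
}

#' Parameter-matched wide U-Net
#'
#' Builds a plain U-Net whose `width_multiplier` is solved by monotone
#' bisection so that its total parameter count falls within `tolerance`
#' of the reference network's (the "similar number of parameters"
#' control).
#'
#' @param reference a built `segmentation_network`
#' @param tolerance allowed relative parameter-count deviation (default 0.1)
#' @param seed optional; see [build_network()]
#' @return a `segmentation_network` with an extra `multiplier` element
#' @export
build_wide_unet <- function(reference, tolerance = 0.1, seed = NULL) {
  stopifnot(inherits(reference, "segmentation_network"))
  target <- n_parameters(reference$net)
  base_spec <- reference$spec
  base_spec$block <- "plain"
  base_spec$placement <- "both"
  base_spec$skip_mode <- "plain"
  params_at <- function(mult) {
    s <- base_spec; s$width_multiplier <- mult
    count_parameters(s)
  }
  lo <- 1.0; hi <- 8.0
  if (params_at(lo) > target * (1 + tolerance))
    stop("reference is smaller than the narrowest admissible wide U-Net")
  if (params_at(hi) < target * (1 - tolerance))
    stop("tolerance unreachable within multiplier bounds [1, 8]")
  best <- lo
  for (it in seq_len(60)) {
    mid <- (lo + hi) / 2
    if (params_at(mid) < target) lo <- mid else hi <- mid
  }
  best <- if (abs(params_at(lo) - target) < abs(params_at(hi) - target)) lo else hi
  if (abs(params_at(best) - target) / target > tolerance)
    stop("tolerance unreachable within multiplier bounds [1, 8]")
  spec <- base_spec
  spec$width_multiplier <- best
  net <- build_network(spec, seed)
  net$multiplier <- best
  net
}

# ---- architecture registry -------------------------------------------------

#' Names understood by the architecture registry
#'
#' @return character vector of canonical architecture names
#' @export
list_architectures <- function() {
  c("unet", "wide_unet", "msunet", "msunet_encoder", "msunet_decoder",
    "res_msunet_0", "res_msunet_1", "attunet", "msattunet", "unetpp",
    "msunetpp")
}

#' Build an architecture by registry name
#'
#' Canonical names: `"unet"`, `"wide_unet"`, `"msunet"` (= `"msunet:37"`),
#' `"msunet_encoder"`, `"msunet_decoder"`, `"res_msunet_0"`,
#' `"res_msunet_1"`, `"attunet"`, `"msattunet"`, `"unetpp"`,
#' `"msunetpp"`. Any block name from [block_config_from_name()] can be
#' substituted after a colon, e.g. `"msunet:37+sum"`, `"msunet:39"`.
#'
#' @param name registry name
#' @param levels,base_width,in_channels,out_classes,batchnorm forwarded to
#'   [network_spec()]
#' @param seed optional; see [build_network()]
#' @param wide_tolerance parameter-parity tolerance for `"wide_unet"`,
#'   whose reference is `msunet:37` at the same dimensions
#' @return a `segmentation_network`
#' @export
build_architecture <- function(name, levels = 5L, base_width = 64L,
                               in_channels = 1L, out_classes = 1L,
                               batchnorm = TRUE, seed = NULL,
                               wide_tolerance = 0.1) {
  sp <- function(...) network_spec(levels = levels, base_width = base_width,
                                   in_channels = in_channels,
                                   out_classes = out_classes,
                                   batchnorm = batchnorm, ...)
  blockname <- if (grepl(":", name, fixed = TRUE))
    sub("^[^:]*:", "", name) else "37"
  key <- sub(":.*$", "", name)
  if (grepl("^res[01]:", name)) { key <- "msunet"; blockname <- name }
  switch(key,
    unet = build_network(sp(block = "plain"), seed),
    wide_unet = {
      ref <- build_architecture(paste0("msunet:", blockname), levels,
                                base_width, in_channels, out_classes,
                                batchnorm)
      build_wide_unet(ref, tolerance = wide_tolerance, seed = seed)
    },
    msunet = build_network(sp(block = blockname), seed),
    msunet_encoder = build_network(sp(block = blockname,
                                      placement = "encoder_only"), seed),
    msunet_decoder = build_network(sp(block = blockname,
                                      placement = "decoder_only"), seed),
    res_msunet_0 = build_network(sp(block = paste0("res0:", blockname)), seed),
    res_msunet_1 = build_network(sp(block = paste0("res1:", blockname)), seed),
    attunet = build_network(sp(block = "plain",
                               skip_mode = "attention_gate"), seed),
    msattunet = build_network(sp(block = blockname,
                                 skip_mode = "attention_gate"), seed),
    unetpp = build_network(sp(block = "plain", skip_mode = "nested"), seed),
    msunetpp = build_network(sp(block = blockname, skip_mode = "nested"),
                             seed),
    stop("unknown architecture name: ", name)
  )
}

# ---- checkpointing ---------------------------------------------------------

#' Save / load a segmentation network
#'
#' The checkpoint embeds the `network_spec` and the flat parameter/buffer
#' state; loading rebuilds the module graph from the spec and restores
#' the state.
#'
#' @param network a `segmentation_network`
#' @param path file path
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "segmentation_network"))
  saveRDS(list(spec = network$spec, multiplier = network$multiplier,
               state = nn_state(network$net)), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$spec)
  nn_load_state(net$net, ck$state)
  net$multiplier <- ck$multiplier
  net
}
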