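#' @useDynLib msunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
NULL

# ---------------------------------------------------------------------------
# Minimal CNN engine.
#
# Activations are dense arrays with dim c(H, W, C, N) (height, width,
# channel, batch). Modules are environments carrying parameters, gradient
# slots (g_<name>), momentum buffers (v_<name>) and forward caches; the
# graph is explicit: every module implements nn_forward() and nn_backward().
# ---------------------------------------------------------------------------

new_module <- function(class, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(class, "nn_module")
  e
}

#' Run a module forward
#'
#' @param m a module built by the block/network constructors
#' @param x input activation array, dim `c(H, W, C, N)`
#' @param training logical; `TRUE` uses batch statistics in batch-norm
#'   layers and caches intermediates for the backward pass
#' @return output activation array
#' @export
nn_forward <- function(m, x, training = TRUE) UseMethod("nn_forward")

#' Backpropagate through a module
#'
#' Consumes the gradient of the loss with respect to the module output,
#' stores parameter gradients inside the module and returns the gradient
#' with respect to the module input. Must follow a `training = TRUE`
#' forward pass.
#'
#' @param m a module
#' @param gy gradient array, same shape as the forward output
#' @return gradient with respect to the forward input
#' @export
nn_backward <- function(m, gy) UseMethod("nn_backward")

# list of primitive (parameter-carrying) layer environments, depth-first
nn_layers <- function(m) UseMethod("nn_layers")

#' Count trainable parameters of a built module or network
#'
#' Walks every primitive layer and sums the lengths of its parameter
#' arrays (convolution weights and biases, batch-norm gains and offsets).
#' This is the brute-force tally used to cross-check the closed-form
#' [count_parameters()] on block configurations.
#'
#' @param m a module or network
#' @return integer parameter count
#' @export
n_parameters <- function(m) {
  tot <- 0
  for (ly in nn_layers(m))
    for (p in ly$params) tot <- tot + length(ly[[p]])
  tot
}

# deep copy (environments are reference objects)
nn_clone <- function(m) unserialize(serialize(m, NULL))

# flat list of parameter and buffer values, for checkpointing
nn_state <- function(m) {
  st <- list()
  for (ly in nn_layers(m)) {
    for (p in c(ly$params, ly$buffers)) st[[length(st) + 1L]] <- ly[[p]]
  }
  st
}

nn_load_state <- function(m, st) {
  i <- 0L
  for (ly in nn_layers(m)) {
    for (p in c(ly$params, ly$buffers)) {
      i <- i + 1L
      stopifnot(length(ly[[p]]) == length(st[[i]]))
      val <- st[[i]]
      attributes(val) <- attributes(ly[[p]])
      assign(p, val, envir = ly)
    }
  }
  invisible(m)
}

# one SGD step with classical momentum; gradients must be populated
sgd_step <- function(m, lr, momentum = 0.9) {
  for (ly in nn_layers(m)) {
    for (p in ly$params) {
      g <- ly[[paste0("g_", p)]]
      if (is.null(g)) next
      vkey <- paste0("v_", p)
      v <- if (is.null(ly[[vkey]])) 0 else ly[[vkey]]
      v <- momentum * v + g
      assign(vkey, v, envir = ly)
      assign(p, ly[[p]] - lr * v, envir = ly)
    }
  }
  invisible(m)
}

# zero every parameter (and reset batch-norm offsets); used to realise
# "zero-initialized block path" identities
nn_zero_parameters <- function(m) {
  for (ly in nn_layers(m))
    for (p in ly$params) assign(p, ly[[p]] * 0, envir = ly)
  invisible(m)
}

# ---- padding arithmetic ----------------------------------------------------

# same-padding for stride-1 convolution; even kernels pad the extra pixel
# on the top/left so spatial dims are always preserved
same_pad <- function(size, dilation) {
  eff <- dilation * (size - 1L) + 1L
  as.integer(ceiling((eff - 1L) / 2))
}

#' Effective receptive width of a kernel
#'
#' @param size kernel side length
#' @param dilation dilation rate (1 = dense)
#' @return `dilation * (size - 1) + 1`
#' @export
receptive_width <- function(size, dilation = 1L) {
  as.integer(dilation * (size - 1L) + 1L)
}

# ---- primitive layers ------------------------------------------------------

# He-normal fan-in initialisation, the convention for ReLU networks
he_init <- function(n, fan_in) rnorm(n, mean = 0, sd = sqrt(2 / fan_in))

conv_layer <- function(size, in_channels, out_channels,
                       dilation = 1L, bias = TRUE, init = c("he", "zero")) {
  init <- match.arg(init)
  size <- as.integer(size); dilation <- as.integer(dilation)
  n <- size * size * in_channels * out_channels
  w <- if (init == "he") he_init(n, size * size * in_channels) else numeric(n)
  W <- array(w, dim = c(size, size, in_channels, out_channels))
  new_module("conv_layer",
             W = W,
             b = if (bias) numeric(out_channels) else NULL,
             params = if (bias) c("W", "b") else "W",
             buffers = character(),
             size = size, dilation = dilation,
             in_channels = as.integer(in_channels),
             out_channels = as.integer(out_channels),
             pad = same_pad(size, dilation))
}

#' @export
nn_forward.conv_layer <- function(m, x, training = TRUE) {
  if (training) m$x <- x
  cpp_conv2d_fwd(x, m$W, m$b, m$dilation, m$pad, m$pad)
}

#' @export
nn_backward.conv_layer <- function(m, gy) {
  r <- cpp_conv2d_bwd(m$x, m$W, gy, !is.null(m$b), m$dilation, m$pad, m$pad, TRUE)
  m$g_W <- r$gW
  if (!is.null(m$b)) m$g_b <- r$gb
  m$x <- NULL
  r$gx
}

#' @export
nn_layers.conv_layer <- function(m) list(m)

bn_layer <- function(channels, momentum = 0.1, eps = 1e-5) {
  new_module("bn_layer",
             gamma = rep(1, channels), beta = rep(0, channels),
             running_mean = rep(0, channels), running_var = rep(1, channels),
             params = c("gamma", "beta"),
             buffers = c("running_mean", "running_var"),
             momentum = momentum, eps = eps)
}

#' @export
nn_forward.bn_layer <- function(m, x, training = TRUE) {
  if (training) {
    st <- cpp_bn_stats(x)
    invstd <- 1 / sqrt(st$var + m$eps)
    m$x <- x; m$mean <- st$mean; m$invstd <- invstd
    m$running_mean <- (1 - m$momentum) * m$running_mean + m$momentum * st$mean
    m$running_var <- (1 - m$momentum) * m$running_var + m$momentum * st$var
    scale <- m$gamma * invstd
    cpp_channel_affine(x, scale, m$beta - st$mean * scale)
  } else {
    scale <- m$gamma / sqrt(m$running_var + m$eps)
    cpp_channel_affine(x, scale, m$beta - m$running_mean * scale)
  }
}

#' @export
nn_backward.bn_layer <- function(m, gy) {
  r <- cpp_bn_bwd(m$x, gy, m$gamma, m$mean, m$invstd)
  m$g_gamma <- r$ggamma; m$g_beta <- r$gbeta
  m$x <- NULL
  r$gx
}

#' @export
nn_layers.bn_layer <- function(m) list(m)

relu_layer <- function() {
  new_module("relu_layer", params = character(), buffers = character())
}

#' @export
nn_forward.relu_layer <- function(m, x, training = TRUE) {
  y <- x
  y[y < 0] <- 0
  if (training) m$mask <- x > 0
  y
}

#' @export
nn_backward.relu_layer <- function(m, gy) {
  g <- gy * m$mask
  m$mask <- NULL
  g
}

#' @export
nn_layers.relu_layer <- function(m) list()

maxpool_layer <- function() {
  new_module("maxpool_layer", params = character(), buffers = character())
}

#' @export
nn_forward.maxpool_layer <- function(m, x, training = TRUE) {
  r <- cpp_maxpool2_fwd(x)
  if (training) { m$idx <- r$idx; m$H <- dim(x)[1]; m$W <- dim(x)[2] }
  r$y
}

#' @export
nn_backward.maxpool_layer <- function(m, gy) {
  g <- cpp_maxpool2_bwd(gy, m$idx, m$H, m$W)
  m$idx <- NULL
  g
}

#' @export
nn_layers.maxpool_layer <- function(m) list()

upconv_layer <- function(in_channels, out_channels) {
  W <- array(he_init(4L * in_channels * out_channels, 4L * in_channels),
             dim = c(2L, 2L, in_channels, out_channels))
  new_module("upconv_layer",
             W = W, b = numeric(out_channels),
             params = c("W", "b"), buffers = character())
}

#' @export
nn_forward.upconv_layer <- function(m, x, training = TRUE) {
  if (training) m$x <- x
  cpp_upconv2_fwd(x, m$W, m$b)
}

#' @export
nn_backward.upconv_layer <- function(m, gy) {
  r <- cpp_upconv2_bwd(m$x, m$W, gy)
  m$g_W <- r$gW; m$g_b <- r$gb
  m$x <- NULL
  r$gx
}

#' @export
nn_layers.upconv_layer <- function(m) list(m)

upsample_layer <- function(method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  new_module("upsample_layer", params = character(), buffers = character(),
             method = if (method == "nearest") 0L else 1L)
}

#' @export
nn_forward.upsample_layer <- function(m, x, training = TRUE) {
  if (training) { m$H <- dim(x)[1]; m$W <- dim(x)[2] }
  cpp_upsample2_fwd(x, m$method)
}

#' @export
nn_backward.upsample_layer <- function(m, gy) {
  cpp_upsample2_bwd(gy, m$H, m$W, m$method)
}

#' @export
nn_layers.upsample_layer <- function(m) list()

# ---- sequential container --------------------------------------------------

nn_sequential <- function(...) {
  children <- list(...)
  if (length(children) == 1L && is.list(children[[1]]) &&
      !inherits(children[[1]], "nn_module"))
    children <- children[[1]]
  new_module("nn_sequential", children = children)
}

#' @export
nn_forward.nn_sequential <- function(m, x, training = TRUE) {
  for (ch in m$children) x <- nn_forward(ch, x, training)
  x
}

#' @export
nn_backward.nn_sequential <- function(m, gy) {
  for (ch in rev(m$children)) gy <- nn_backward(ch, gy)
  gy
}

#' @export
nn_layers.nn_sequential <- function(m) {
  do.call(c, lapply(m$children, nn_layers))
}

# ---- channel concatenation helpers ----------------------------------------

concat_channels <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], numeric(1))
  y <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[3]
    y[, , at + seq_len(cc), ] <- x
    at <- at + cc
  }
  y
}

split_channels <- function(g, widths) {
  out <- vector("list", length(widths))
  at <- 0L
  for (i in seq_along(widths)) {
    out[[i]] <- g[, , at + seq_len(widths[i]), , drop = FALSE]
    at <- at + widths[i]
  }
  out
}
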