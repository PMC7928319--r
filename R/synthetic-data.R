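# Seedable synthetic image/mask generation emulating four binary
# segmentation modalities: lesion-like blobs (ultrasound/dermoscopy
# analogue), membrane networks (electron-microscopy analogue), paired
# large organs (chest-radiograph lung-field analogue) and dense small
# nuclei (stained-histology analogue), plus the six-subset / five-fold
# split protocol.

#' Synthetic dataset style
#'
#' @param name one of `"blobs"` (one or more lesion-like ellipses,
#'   speckled ultrasound-style texture; foreground = lesion),
#'   `"membranes"` (tessellated cell interiors separated by dark
#'   boundaries; foreground = interiors, background = membranes),
#'   `"bilobe"` (two large smooth lung-field-like regions; foreground =
#'   the two lobes) or `"nuclei"` (many small dark blobs on a light
#'   stained background; foreground = nuclei)
#' @param image_size square image side in pixels, divisible by 16
#' @param channels 1 (grayscale) or 3 (RGB); defaults per style
#' @param noise_sigma additive Gaussian noise standard deviation
#' @param speckle multiplicative speckle factor (ultrasound-like texture)
#' @param n_objects length-2 integer range of foreground objects per
#'   image (ignored by `membranes` and `bilobe`)
#' @return a `synthetic_style` object
#' @export
synthetic_style <- function(name = c("blobs", "membranes", "bilobe", "nuclei"),
                            image_size = 128L, channels = NULL,
                            noise_sigma = NULL, speckle = NULL,
                            n_objects = NULL) {
  name <- match.arg(name)
  image_size <- as.integer(image_size)
  if (image_size %% 16L != 0L) stop("image_size must be divisible by 16")
  defaults <- switch(name,
    blobs = list(channels = 1L, noise_sigma = 0.03, speckle = 0.25,
                 n_objects = c(1L, 3L)),
    membranes = list(channels = 1L, noise_sigma = 0.05, speckle = 0,
                     n_objects = c(12L, 20L)),
    bilobe = list(channels = 1L, noise_sigma = 0.04, speckle = 0,
                  n_objects = c(2L, 2L)),
    nuclei = list(channels = 3L, noise_sigma = 0.04, speckle = 0,
                  n_objects = c(10L, 25L)))
  channels <- if (is.null(channels)) defaults$channels else as.integer(channels)
  if (!channels %in% c(1L, 3L)) stop("channels must be 1 or 3")
  noise_sigma <- if (is.null(noise_sigma)) defaults$noise_sigma else noise_sigma
  speckle <- if (is.null(speckle)) defaults$speckle else speckle
  n_objects <- if (is.null(n_objects)) defaults$n_objects else as.integer(n_objects)
  if (noise_sigma < 0 || speckle < 0) stop("noise parameters must be >= 0")
  structure(list(name = name, image_size = image_size, channels = channels,
                 noise_sigma = noise_sigma, speckle = speckle,
                 n_objects = n_objects),
            class = "synthetic_style")
}

# separable-equivalent Gaussian blur through the convolution kernel
gaussian_blur <- function(img, sigma = 1, size = 5L) {
  ax <- seq_len(size) - (size + 1) / 2
  k1 <- exp(-ax^2 / (2 * sigma^2))
  k2 <- outer(k1, k1); k2 <- k2 / sum(k2)
  W <- array(k2, dim = c(size, size, 1L, 1L))
  H <- nrow(img); Wd <- ncol(img)
  x <- array(img, dim = c(H, Wd, 1L, 1L))
  pad <- same_pad(size, 1L)
  matrix(cpp_conv2d_fwd(x, W, NULL, 1L, pad, pad), H, Wd)
}

# rotated-ellipse membership on the pixel grid (row-major, origin
# top-left, 0-based centers in pixel units)
ellipse_mask <- function(size, cx, cy, rx, ry, angle) {
  xs <- matrix(rep(0:(size - 1), each = size), size, size)   # column coord
  ys <- matrix(rep(0:(size - 1), times = size), size, size)  # row coord
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  (u / rx)^2 + (v / ry)^2 <= 1
}

random_ellipses <- function(size, k, r_range) {
  m <- matrix(FALSE, size, size)
  for (i in seq_len(k)) {
    cx <- runif(1, 0.15, 0.85) * size
    cy <- runif(1, 0.15, 0.85) * size
    rx <- runif(1, r_range[1], r_range[2]) * size
    ry <- runif(1, r_range[1], r_range[2]) * size
    m <- m | ellipse_mask(size, cx, cy, rx, ry, runif(1, 0, pi))
  }
  m
}

synth_blobs <- function(sty) {
  s <- sty$image_size
  k <- sample(sty$n_objects[1]:sty$n_objects[2], 1)
  mask <- random_ellipses(s, k, c(0.08, 0.22))
  img <- 0.62 - 0.38 * mask            # hypoechoic lesion: darker than bg
  img <- gaussian_blur(img, sigma = 1.5)
  list(img = img, mask = mask)
}

synth_membranes <- function(sty) {
  s <- sty$image_size
  k <- sample(sty$n_objects[1]:sty$n_objects[2], 1)
  cx <- runif(k, 0, s - 1); cy <- runif(k, 0, s - 1)
  xs <- matrix(rep(0:(s - 1), each = s), s, s)
  ys <- matrix(rep(0:(s - 1), times = s), s, s)
  d1 <- matrix(Inf, s, s); d2 <- matrix(Inf, s, s)
  for (i in seq_len(k)) {
    d <- (xs - cx[i])^2 + (ys - cy[i])^2
    closer <- d < d1
    d2 <- ifelse(closer, d1, pmin(d2, d))
    d1 <- pmin(d1, d)
  }
  # membrane = ridge where the two nearest generators are near-equidistant
  ridge <- (sqrt(d2) - sqrt(d1)) < max(1.5, s / 96)
  mask <- !ridge                       # foreground = cell interiors
  img <- 0.25 + 0.5 * mask             # interiors bright, membranes dark
  img <- gaussian_blur(img, sigma = 0.8)
  list(img = img, mask = mask)
}

synth_bilobe <- function(sty) {
  s <- sty$image_size
  m1 <- ellipse_mask(s, runif(1, 0.28, 0.33) * s, runif(1, 0.45, 0.55) * s,
                     runif(1, 0.13, 0.17) * s, runif(1, 0.26, 0.33) * s,
                     runif(1, -0.15, 0.15))
  m2 <- ellipse_mask(s, runif(1, 0.67, 0.72) * s, runif(1, 0.45, 0.55) * s,
                     runif(1, 0.13, 0.17) * s, runif(1, 0.26, 0.33) * s,
                     runif(1, -0.15, 0.15))
  mask <- m1 | m2
  img <- 0.72 - 0.42 * mask            # radiolucent lung fields: dark
  img <- gaussian_blur(img, sigma = 2)
  list(img = img, mask = mask)
}

synth_nuclei <- function(sty) {
  s <- sty$image_size
  k <- sample(sty$n_objects[1]:sty$n_objects[2], 1)
  mask <- random_ellipses(s, k, c(0.02, 0.05))
  img <- 0.82 - 0.5 * mask             # hematoxylin-dark nuclei on light bg
  img <- gaussian_blur(img, sigma = 0.8)
  list(img = img, mask = mask)
}

expand_channels <- function(img, sty) {
  s <- sty$image_size
  if (sty$channels == 1L) return(array(img, dim = c(s, s, 1L)))
  # simple stain-like tinting: scale the gray field per channel
  tint <- switch(sty$name,
                 nuclei = c(1.0, 0.85, 1.05),
                 c(1.0, 1.0, 1.0))
  out <- array(0, dim = c(s, s, 3L))
  for (c in 1:3) out[, , c] <- pmin(1, img * tint[c])
  out
}

#' Generate a synthetic image/mask dataset
#'
#' Fully deterministic under a fixed `(style, n, seed)`; every mask has at
#' least one foreground pixel and a foreground fraction strictly inside
#' (0, 1); images are scaled to \[0, 1\] and quantized to the 8-bit grid
#' so that disk round-trips are lossless.
#'
#' @param style a [synthetic_style()] (or a style name string)
#' @param n number of image/mask pairs (>= 1)
#' @param seed integer RNG seed
#' @return a `seg_dataset`: list with `images` (H x W x C arrays in
#'   \[0, 1\]), `masks` (H x W matrices in \{0, 1\}), `style`, `seed`
#' @export
synthesize_dataset <- function(style, n, seed = 1L) {
  if (is.character(style)) style <- synthetic_style(style)
  stopifnot(inherits(style, "synthetic_style"))
  if (n < 1) stop("n must be >= 1")
  set.seed(as.integer(seed))
  gen <- switch(style$name, blobs = synth_blobs, membranes = synth_membranes,
                bilobe = synth_bilobe, nuclei = synth_nuclei)
  images <- vector("list", n); masks <- vector("list", n)
  s <- style$image_size
  for (i in seq_len(n)) {
    repeat {
      sm <- gen(style)
      ff <- mean(sm$mask)
      if (ff > 0 && ff < 1) break     # guard: degenerate draws are redrawn
    }
    img <- sm$img
    if (style$speckle > 0)
      img <- img * (1 + style$speckle * matrix(rnorm(s * s), s, s))
    if (style$noise_sigma > 0)
      img <- img + style$noise_sigma * matrix(rnorm(s * s), s, s)
    img <- pmin(1, pmax(0, img))
    arr <- expand_channels(img, style)
    arr <- round(arr * 255) / 255      # 8-bit grid: lossless disk round-trip
    images[[i]] <- arr
    masks[[i]] <- matrix(as.numeric(sm$mask), s, s)
  }
  structure(list(images = images, masks = masks, style = style,
                 seed = as.integer(seed)),
            class = "seg_dataset")
}

#' @export
length.seg_dataset <- function(x) length(x$images)

#' @export
print.seg_dataset <- function(x, ...) {
  cat(sprintf("synthetic segmentation dataset: %d pairs, style %s, %dx%d, %d channel(s)\n",
              length(x$images), x$style$name, x$style$image_size,
              x$style$image_size, x$style$channels))
  invisible(x)
}

# stack dataset entries into network-ready arrays
dataset_batch <- function(data, indices) {
  d <- dim(data$images[[indices[1]]])
  n <- length(indices)
  x <- array(0, dim = c(d[1], d[2], d[3], n))
  y <- array(0, dim = c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- data$images[[indices[i]]]
    y[, , 1L, i] <- data$masks[[indices[i]]]
  }
  list(x = x, y = y)
}

#' Six-subset split with five-fold cross-validation
#'
#' Randomly divides `n` images into six near-equal subsets; one subset
#' (the sixth by default) is held out as the test set and the remaining
#' pool is split into five folds whose validation sets partition the
#' pool, giving a 4:1 train:validation ratio within each fold.
#'
#' @param n number of images (>= 12)
#' @param seed integer RNG seed
#' @param test_subset which of the six subsets is the test set
#' @return a `split_plan`: `subset` (id 1..6 per image), `test`
#'   (indices), `folds` (five `list(train, val)` entries)
#' @export
make_splits <- function(n, seed = 1L, test_subset = 6L) {
  n <- as.integer(n)
  if (n < 12L) stop("n too small to populate 6 subsets (need n >= 12)")
  if (!test_subset %in% 1:6) stop("test_subset must be in 1..6")
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  subset <- integer(n)
  subset[perm] <- rep(1:6, length.out = n)
  test <- which(subset == test_subset)
  pool <- which(subset != test_subset)
  poolperm <- sample(pool)
  foldid <- rep(1:5, length.out = length(pool))
  folds <- lapply(1:5, function(k) {
    val <- sort(poolperm[foldid == k])
    list(train = sort(setdiff(pool, val)), val = val)
  })
  structure(list(n = n, subset = subset, test_subset = as.integer(test_subset),
                 test = test, folds = folds, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split plan: n=%d, six subsets (sizes %s), test subset %d (%d images)\n",
              x$n, paste(tabulate(x$subset, 6), collapse = "/"),
              x$test_subset, length(x$test)))
  for (k in seq_along(x$folds))
    cat(sprintf("  fold %d: %d train / %d val\n", k,
                length(x$folds[[k]]$train), length(x$folds[[k]]$val)))
  invisible(x)
}
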