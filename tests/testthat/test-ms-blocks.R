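# Multi-scale block construction, fusion, residual wiring and parameter
# accounting.

test_that("block family enumeration matches the combinatorial definition", {
  cfgs <- enumerate_block_configs(8, 16)
  expect_length(cfgs, 31L)

  # independent oracle: all non-empty subsets of {1,2,5,7,9} joined with 3
  others <- c(1, 2, 5, 7, 9)
  expected <- character()
  for (sz in 1:5)
    expected <- c(expected, vapply(utils::combn(others, sz, simplify = FALSE),
                                   function(s) paste(sort(c(3, s)), collapse = ""),
                                   character(1)))
  expect_setequal(names(cfgs), expected)

  expect_true("37" %in% names(cfgs))
  k37 <- vapply(cfgs[["37"]]$kernels, function(k) k$size, integer(1))
  expect_equal(k37, c(3L, 7L))

  two_kernel <- names(cfgs)[vapply(cfgs, function(c) length(c$kernels),
                                   integer(1)) == 2L]
  expect_setequal(two_kernel, c("13", "23", "35", "37", "39"))

  for (cfg in cfgs) {
    expect_identical(cfg$fusion, "concat")
    expect_identical(cfg$residual, "none")
    expect_true(3L %in% vapply(cfg$kernels, function(k) k$size, integer(1)))
  }
})

test_that("kernel and config validation rejects malformed inputs", {
  expect_error(kernel_spec(4), "kernel size")
  expect_error(kernel_spec(3, 0), "dilation")
  expect_error(ms_block_config(numeric(0), 8, 8), "non-empty")
  expect_error(ms_block_config(c(3, 7, 9), 8, 8, topology = "serial"),
               "exactly two")
  expect_error(ms_block_config(c(3, 7), 8, 8, topology = "serial",
                               residual = "additive_0"), "parallel")
  expect_equal(receptive_width(3, 3), 7L)
  expect_equal(receptive_width(9, 1), 9L)
})

test_that("a conv branch honours the shape contract and linearity", {
  set.seed(1)
  br <- build_conv_branch(kernel_spec(3), 8, 16)
  y <- nn_forward(br, rand_input(32, 32, 8), training = FALSE)
  expect_equal(dim(y), c(32L, 32L, 16L, 1L))

  # zero weights and biases give identically zero output
  br0 <- build_conv_branch(kernel_spec(3), 8, 16, batchnorm = FALSE)
  msunet:::nn_zero_parameters(br0)
  y0 <- nn_forward(br0, rand_input(16, 16, 8), training = FALSE)
  expect_true(all(y0 == 0))

  # closed form 2 x (k^2 c_in c_out + c_out) per conv, no normalization
  brb <- build_conv_branch(kernel_spec(3), 8, 16, batchnorm = FALSE)
  expect_equal(n_parameters(brb),
               (3 * 3 * 8 * 16 + 16) + (3 * 3 * 16 * 16 + 16))
  expect_equal(n_parameters(brb), 3488L)
})

test_that("parallel fusion concatenates branch outputs before the 1x1 reduction", {
  set.seed(2)
  cfg <- block_config_from_name("37", 64, 64)
  blk <- build_block(cfg)
  x <- rand_input(48, 48, 64, 2)
  y <- multiscale_forward(x, blk)
  expect_equal(dim(y), c(48L, 48L, 64L, 2L))
  # fusion conv consumes the concatenated width 2 * 64
  expect_equal(dim(blk$fusion$children[[1]]$W)[3], 128L)

  expect_error(multiscale_forward(rand_input(48, 48, 32), blk), "channels")
})

test_that("single-branch blocks make concat and sum fusion identical", {
  x <- rand_input(24, 24, 8, 1, seed = 3)
  set.seed(10)
  bc <- build_block(ms_block_config(3, 8, 16, fusion = "concat"))
  set.seed(10)
  bs <- build_block(ms_block_config(3, 8, 16, fusion = "sum"))
  expect_identical(nn_forward(bc, x, training = FALSE),
                   nn_forward(bs, x, training = FALSE))
})

test_that("zeroed branches with an identity-biased fusion conv give a constant map", {
  cfg <- ms_block_config(c(3, 7), 8, 4, batchnorm = FALSE)
  blk <- build_block(cfg)
  msunet:::nn_zero_parameters(blk)
  b <- c(0.3, 0.7, 0.1, 0.9)
  blk$fusion$children[[1]]$b <- b
  y <- nn_forward(blk, rand_input(16, 16, 8), training = FALSE)
  for (c in 1:4) expect_true(all(y[, , c, ] == b[c]))
})

test_that("branches are independent: same input, unshared weights", {
  set.seed(4)
  cfg <- block_config_from_name("37", 4, 4, batchnorm = TRUE)
  blk <- build_block(cfg)
  x <- rand_input(16, 16, 4)
  y1 <- nn_forward(blk, x, training = FALSE)
  # perturbing one branch changes the block output ...
  blk$branches[[2]]$children[[1]]$W <- blk$branches[[2]]$children[[1]]$W + 0.5
  y2 <- nn_forward(blk, x, training = FALSE)
  expect_false(isTRUE(all.equal(y1, y2)))
  # ... but never the other branch's own intermediate output
  b1_before <- nn_forward(blk$branches[[1]], x, training = FALSE)
  blk$branches[[2]]$children[[1]]$W <- blk$branches[[2]]$children[[1]]$W * 0
  b1_after <- nn_forward(blk$branches[[1]], x, training = FALSE)
  expect_identical(b1_before, b1_after)
})

test_that("serial arrangements apply the two kernel stages in sequence", {
  set.seed(5)
  x <- rand_input(32, 32, 8)
  y37 <- serial_forward(x, c(3, 7), out_channels = 8)
  y73 <- serial_forward(x, c(7, 3), out_channels = 8)
  expect_equal(dim(y37), dim(x))
  expect_equal(dim(y73), dim(x))
  # distinct parameterizations, not the same operator
  expect_false(isTRUE(all.equal(y37, y73)))

  # [3,3] is structurally a plain 4-conv stack
  cfg33 <- ms_block_config(c(3, 3), 8, 8, topology = "serial")
  blk33 <- msunet:::build_serial_block(cfg33)
  convs <- Filter(function(l) inherits(l, "conv_layer"),
                  msunet:::nn_layers(blk33))
  expect_length(convs, 4L)
  expect_true(all(vapply(convs, function(l) l$size, integer(1)) == 3L))

  # zero weights give zero output
  cfg <- ms_block_config(c(3, 7), 8, 8, topology = "serial",
                         batchnorm = FALSE)
  blk <- msunet:::build_serial_block(cfg)
  msunet:::nn_zero_parameters(blk)
  expect_true(all(nn_forward(blk, x, training = FALSE) == 0))

  expect_error(serial_forward(x, c(3, 5, 7)), "exactly 2")
})

test_that("the dilated substitution preserves the receptive field and sheds parameters", {
  cfg <- block_config_from_name("37", 8, 16)
  dil <- dilated_variant(cfg)
  sizes <- vapply(dil$kernels, function(k) k$size, integer(1))
  dils <- vapply(dil$kernels, function(k) k$dilation, integer(1))
  expect_equal(sizes, c(3L, 3L))
  expect_equal(dils, c(1L, 3L))
  expect_equal(receptive_width(3, 3), 7L)
  expect_lt(count_parameters(dil), count_parameters(cfg))

  expect_error(dilated_variant(block_config_from_name("35", 8, 16)),
               "7x7")
  # forward still conserves shape
  y <- multiscale_forward(rand_input(32, 32, 8), build_block(dil))
  expect_equal(dim(y), c(32L, 32L, 16L, 1L))
})

test_that("residual wiring matches both variants' contracts", {
  # concat variant: input joins the branch outputs before the 1x1 fusion
  cfg1 <- block_config_from_name("res1:37", 64, 64)
  blk1 <- build_block(cfg1)
  expect_equal(dim(blk1$fusion$children[[1]]$W)[3], 192L)
  x <- rand_input(16, 16, 64, 1, seed = 6)
  expect_equal(dim(residual_multiscale_forward(x, blk1)), dim(x))

  # additive variant with a zeroed block path reproduces the input bitwise
  cfg0 <- block_config_from_name("res0:37", 8, 8)
  blk0 <- build_block(cfg0)
  msunet:::nn_zero_parameters(blk0)
  x <- rand_input(16, 16, 8, 2, seed = 7)
  expect_identical(residual_multiscale_forward(x, blk0), x)

  # channel-changing additive variant uses the 1x1 projection
  cfg0b <- block_config_from_name("res0:37", 8, 16)
  blk0b <- build_block(cfg0b)
  expect_false(is.null(blk0b$proj))
  expect_equal(dim(residual_multiscale_forward(rand_input(16, 16, 8), blk0b)),
               c(16L, 16L, 16L, 1L))

  # concat variant, zero fusion weights, bias b: constant map b
  cfgc <- ms_block_config(c(3, 7), 4, 2, residual = "concat_1",
                          batchnorm = FALSE)
  blkc <- build_block(cfgc)
  msunet:::nn_zero_parameters(blkc)
  blkc$fusion$children[[1]]$b <- c(0.25, 0.5)
  y <- nn_forward(blkc, rand_input(8, 8, 4), training = FALSE)
  expect_true(all(y[, , 1, ] == 0.25) && all(y[, , 2, ] == 0.5))

  expect_error(residual_multiscale_forward(x, build_block(
    block_config_from_name("37", 8, 8))), "no residual")
})

test_that("closed-form parameter counts agree with a brute-force walk", {
  # hand tally: single-branch "3", 1 -> 1, biased convs, no normalization
  cfg1 <- ms_block_config(3, 1, 1, batchnorm = FALSE)
  expect_equal(count_parameters(cfg1), (9 + 1) + (9 + 1) + (1 + 1))
  expect_equal(count_parameters(cfg1), 22L)

  # monotone in the kernel set at equal widths
  expect_gt(count_parameters(block_config_from_name("37", 8, 8)),
            count_parameters(block_config_from_name("3", 8, 8)))

  # oracle equivalence across the whole family at widths 8 -> 16
  set.seed(8)
  for (cfg in enumerate_block_configs(8, 16))
    expect_equal(count_parameters(cfg), n_parameters(build_block(cfg)))
  # and for the variants
  for (nm in c("37+sum", "37+concatenated", "73+concatenated", "37+dilated",
               "res0:37", "res1:37")) {
    cfg <- block_config_from_name(nm, 8, 16)
    expect_equal(count_parameters(cfg), n_parameters(build_block(cfg)),
                 info = nm)
  }
})

test_that("every branch parameter receives a gradient after one backward pass", {
  set.seed(9)
  blk <- build_block(block_config_from_name("137", 4, 8))
  x <- rand_input(16, 16, 4, 2)
  y <- nn_forward(blk, x, training = TRUE)
  nn_backward(blk, array(rnorm(length(y)), dim = dim(y)))
  for (ly in msunet:::nn_layers(blk)) {
    for (pn in ly$params) {
      g <- ly[[paste0("g_", pn)]]
      expect_false(is.null(g))
      expect_true(all(is.finite(g)))
      expect_true(any(g != 0) ||
                    identical(pn, "b"))  # conv bias before BN: zero gradient
    }
  }
})
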