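# Network assembly: U-shaped variants, attention gates, nested skips,
# parameter parity, checkpointing.

named_architectures <- c("unet", "wide_unet", "msunet", "msunet_encoder",
                         "msunet_decoder", "msunet:37+sum",
                         "msunet:37+concatenated", "msunet:73+concatenated",
                         "msunet:37+dilated", "res_msunet_0", "res_msunet_1",
                         "attunet", "msattunet", "unetpp", "msunetpp")

test_that("every named architecture builds, conserves shape, and learns on one batch", {
  x <- rand_input(32, 32, 1, 2, seed = 20)
  set.seed(21)
  y <- array(rbinom(length(x) , 1, 0.3), dim = dim(x))
  for (a in named_architectures) {
    net <- build_architecture(a, levels = 3, base_width = 4, seed = 22)
    p <- network_forward(net, x)
    expect_equal(dim(p), dim(x), info = a)
    expect_true(all(p >= 0 & p <= 1), info = a)

    bce <- function() {
      lg <- nn_forward(net$net, x, training = TRUE)
      mean(pmax(lg, 0) - lg * y + log1p(exp(-abs(lg))))
    }
    l0 <- bce()
    lg <- nn_forward(net$net, x, training = TRUE)
    pr <- 1 / (1 + exp(-lg))
    nn_backward(net$net, (pr - y) / length(lg))
    msunet:::sgd_step(net$net, lr = 1e-2, momentum = 0.9)
    expect_lt(bce(), l0)
  }
})

test_that("rebuilding from the same spec and seed is bitwise deterministic", {
  a <- build_architecture("msunet", levels = 3, base_width = 4, seed = 123)
  b <- build_architecture("msunet", levels = 3, base_width = 4, seed = 123)
  expect_identical(msunet:::nn_state(a$net), msunet:::nn_state(b$net))
  x <- rand_input(16, 16, 1, 1, seed = 1)
  expect_identical(network_forward(a, x), network_forward(b, x))
})

test_that("forward rejects inputs not divisible by the downsampling factor", {
  net <- build_architecture("unet", levels = 3, base_width = 4)
  expect_error(network_forward(net, rand_input(30, 30, 1)), "divisible")
  expect_error(network_forward(net, rand_input(32, 32, 3)), "channels")
})

test_that("multi-scale replacement strictly adds parameters over the plain network", {
  plain <- network_spec(levels = 3, base_width = 8, block = "plain")
  ms <- network_spec(levels = 3, base_width = 8, block = "37")
  expect_gt(count_parameters(ms), count_parameters(plain))
  enc <- network_spec(levels = 3, base_width = 8, block = "37",
                      placement = "encoder_only")
  dec <- network_spec(levels = 3, base_width = 8, block = "37",
                      placement = "decoder_only")
  expect_gt(count_parameters(ms), count_parameters(enc))
  expect_gt(count_parameters(ms), count_parameters(dec))
  expect_gt(count_parameters(enc), count_parameters(plain))
})

test_that("closed-form network counts equal a brute-force parameter walk", {
  for (a in c("unet", "msunet", "attunet", "msunetpp", "res_msunet_0",
              "msunet:37+sum", "msunet_decoder")) {
    net <- build_architecture(a, levels = 3, base_width = 4, seed = 30)
    expect_equal(count_parameters(net$spec), n_parameters(net$net), info = a)
  }
  # and with bilinear upsampling
  sp <- network_spec(levels = 3, base_width = 4, block = "37",
                     upsampling = "bilinear")
  expect_equal(count_parameters(sp), n_parameters(build_network(sp)$net))
})

test_that("the wide U-Net matches the reference parameter count within tolerance", {
  ref <- build_architecture("msunet", levels = 4, base_width = 16, seed = 31)
  wide <- build_wide_unet(ref, tolerance = 0.10, seed = 32)
  pr <- n_parameters(ref$net)
  pw <- n_parameters(wide$net)
  expect_lte(abs(pw - pr) / pr, 0.10)
  expect_identical(wide$spec$block, "plain")

  # a plain reference self-matches with multiplier ~ 1
  plain <- build_architecture("unet", levels = 3, base_width = 8)
  self <- build_wide_unet(plain, tolerance = 0.10)
  expect_lt(abs(self$multiplier - 1), 0.05)

  # parameter count is monotone in the multiplier
  sp <- network_spec(levels = 3, base_width = 8, block = "plain")
  counts <- vapply(c(1, 1.5, 2, 3), function(m) {
    sp$width_multiplier <- m; as.numeric(count_parameters(sp))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("the attention gate modulates the skip path as a [0,1] coefficient field", {
  set.seed(33)
  skip <- rand_input(32, 32, 64)
  gate <- rand_input(16, 16, 128)
  g <- msunet:::build_attention_gate(64, 128, ratio = 2)

  out <- attention_gate(skip, gate, g)
  expect_equal(dim(out), dim(skip))

  # coefficients forced to 1 (saturated sigmoid): identity gate
  msunet:::nn_zero_parameters(g)
  g$psi$b <- 40
  expect_identical(attention_gate(skip, gate, g), skip)
  # driven to 0 (saturated the other way): vanishing map
  g$psi$b <- -800
  expect_true(all(attention_gate(skip, gate, g) == 0))

  expect_error(attention_gate(skip, rand_input(12, 12, 8)), "power of 2")
})

test_that("nested-skip networks have the triangular node layout", {
  for (L in c(2, 3, 4)) {
    net <- build_msunetpp(network_spec(levels = L, base_width = 2,
                                       block = "37"), seed = 34)
    n_nodes <- length(net$net$bb) +
      sum(vapply(net$net$nodes, length, integer(1)))
    expect_equal(n_nodes, L * (L + 1) / 2)
  }
  net <- build_msunetpp(network_spec(levels = 3, base_width = 4,
                                     block = "37"), seed = 35)
  p <- network_forward(net, rand_input(32, 32, 1))
  expect_equal(dim(p), c(32L, 32L, 1L, 1L))
  # "plain" reduces to the standard nested network (fewer parameters)
  plain <- build_msunetpp(network_spec(levels = 3, base_width = 4,
                                       block = "plain"))
  expect_lt(n_parameters(plain$net), n_parameters(net$net))
})

test_that("checkpoints round-trip the spec and the full parameter state", {
  net <- build_architecture("msattunet", levels = 3, base_width = 4, seed = 36)
  x <- rand_input(16, 16, 1, 1, seed = 2)
  p0 <- network_forward(net, x)
  f <- tempfile(fileext = ".rds")
  save_network(net, f)
  re <- load_network(f)
  expect_identical(network_forward(re, x), p0)
  expect_equal(re$spec, net$spec)
  unlink(f)
})
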