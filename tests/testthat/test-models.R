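test_that("network outputs live on the simplex at every location", {
  set.seed(41)
  net <- build_unet(net_config(num_classes = 3, seed = 1))
  p <- net$forward(array(rnorm(16 * 16), c(1, 16, 16)), train = FALSE)
  expect_equal(apply(p, c(2, 3), sum), matrix(1, 16, 16))
  expect_true(all(p >= 0 & p <= 1))
  net3 <- build_unet(net_config(in_channels = 3, num_classes = 3,
                                dims = 3, seed = 2))
  p3 <- net3$forward(array(rnorm(3 * 8 * 16 * 16), c(3, 8, 16, 16)),
                     train = FALSE)
  expect_equal(dim(p3), c(3L, 8L, 16L, 16L))
  expect_equal(apply(p3, c(2, 3, 4), sum), array(1, c(8, 16, 16)),
               tolerance = 1e-12)
})

test_that("coarse network keeps spatial shape and handles padding", {
  net <- build_coarse_net(net_config(num_classes = 2, seed = 3))
  set.seed(42)
  for (side in c(64L, 96L, 18L)) {   # 18 exercises the internal padding
    out <- net$forward(array(rnorm(side * side), c(1, side, side)),
                       train = FALSE)
    expect_equal(dim(out$probs), c(2L, side, side))
    expect_equal(dim(out$sdf), c(side, side))
    expect_equal(apply(out$probs, c(2, 3), sum), matrix(1, side, side))
    expect_true(all(abs(out$sdf) <= 1))
  }
})

test_that("builds are deterministic in the seed; pairs differ", {
  cfg <- net_config(num_classes = 3, seed = 11)
  expect_equal(param_checksum(build_unet(cfg)),
               param_checksum(build_unet(cfg)))
  pr <- build_model_pair(cfg, 1, 2)
  expect_false(param_checksum(pr$net_a) == param_checksum(pr$net_b))
  cc <- net_config(num_classes = 2, seed = 5)
  expect_equal(param_checksum(build_coarse_net(cc)),
               param_checksum(build_coarse_net(cc)))
  # eval-mode forward is deterministic
  net <- build_unet(cfg)
  x <- array(rnorm(16 * 16), c(1, 16, 16))
  expect_identical(net$forward(x, train = FALSE),
                   net$forward(x, train = FALSE))
})

test_that("gradients agree with finite differences through every layer type", {
  set.seed(43)
  net <- build_unet(net_config(base_channels = 2, num_classes = 3,
                               seed = 7))
  x <- array(rnorm(16 * 16), c(1, 16, 16))
  y <- matrix(sample(0:2, 256, TRUE), 16, 16)
  p <- net$forward(x, train = TRUE)
  jcps:::zero_grads(net)
  net$backward(jcps:::cross_entropy_grad(y, p))
  eps <- 1e-5
  for (li in c(1, 4, 8, 13, 19)) {
    l <- net$layers_flat[[li]]
    if (!length(l$params)) next
    nm <- names(l$params)[1]
    pi <- 1L
    orig <- l$params[[nm]][pi]
    l$params[[nm]][pi] <- orig + eps
    lp <- cross_entropy_loss(y, net$forward(x, train = TRUE))
    l$params[[nm]][pi] <- orig - eps
    lm <- cross_entropy_loss(y, net$forward(x, train = TRUE))
    l$params[[nm]][pi] <- orig
    num <- (lp - lm) / (2 * eps)
    expect_equal(l$grads[[nm]][pi], num, tolerance = 1e-5,
                 label = paste("layer", li, l$type))
  }
})

test_that("tiny instances run a forward+backward pass quickly", {
  net <- build_unet(net_config(base_channels = 4, depth = 2,
                               num_classes = 3, seed = 1))
  x <- array(rnorm(96 * 96), c(1, 96, 96))
  t2 <- system.time({
    p <- net$forward(x, train = TRUE)
    net$backward(p * 0.01)
  })["elapsed"]
  expect_lt(t2, 1)
  net3 <- build_unet(net_config(in_channels = 3, base_channels = 4,
                                depth = 2, num_classes = 3, dims = 3,
                                seed = 1))
  x3 <- array(rnorm(3 * 16 * 48 * 48), c(3, 16, 48, 48))
  t3 <- system.time({
    p3 <- net3$forward(x3, train = TRUE)
    net3$backward(p3 * 0.01)
  })["elapsed"]
  expect_lt(t3, 1)
})

test_that("undersized or indivisible inputs are rejected", {
  net <- build_unet(net_config(num_classes = 3, depth = 2, seed = 1))
  expect_error(net$forward(array(0, c(1, 6, 6)), train = FALSE),
               "multiples")
})
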