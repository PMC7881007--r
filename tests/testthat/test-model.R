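test_that("conv/pool length arithmetic and delta kernels behave", {
  expect_equal(nrow(conv1d_valid(runif(235), runif(7), stride = 5)), 46)
  expect_equal(nrow(maxpool1d(matrix(runif(46), ncol = 1), 3, 2)), 22)
  expect_equal(nrow(maxpool1d(matrix(runif(4), ncol = 1), 3, 1)), 2)

  # delta kernel: a centred single 1 reproduces a shifted slice
  x <- runif(40)
  k <- c(0, 0, 1, 0, 0)
  out <- conv1d_valid(x, k, stride = 1)
  expect_equal(as.numeric(out), x[3:38])

  # monotone input: pooling takes the strided window tails
  mono <- 1:20
  expect_equal(maxpool1d(mono, 3, 2), mono[seq(3, 19, by = 2)])
  # constant input: constant output
  expect_true(all(maxpool1d(rep(2.5, 10), 3, 1) == 2.5))
})

test_that("vectorised convolutions match naive loop oracles", {
  set.seed(21)
  x <- matrix(runif(30 * 3, -1, 1), 30, 3)
  kern <- array(runif(5 * 3 * 4, -1, 1), c(5, 3, 4))
  bias <- runif(4)
  got <- conv1d_valid(x, kern, stride = 2, bias = bias)
  expect_lt(max(abs(got - oracle_conv1d(x, kern, 2, bias))), 1e-10)

  got_p <- maxpool1d(x, 3, 2)
  expect_lt(max(abs(got_p - oracle_maxpool1d(x, 3, 2))), 1e-12)

  # 2-D stages through the internal batched implementations
  X2 <- array(runif(1 * 20 * 5 * 2, -1, 1), c(1, 20, 5, 2))
  K2 <- array(runif(7 * 3 * 2 * 3, -1, 1), c(7, 3, 2, 3))
  b2 <- runif(3)
  f2 <- pwcnet:::conv2d_forward(X2, K2, b2, c(5, 1))
  want2 <- oracle_conv2d(array(X2[1, , , ], dim(X2)[2:4]), K2, c(5, 1), b2)
  expect_lt(max(abs(array(f2$out[1, , , ], dim(f2$out)[2:4]) - want2)), 1e-10)

  p2 <- pwcnet:::maxpool2d_forward(f2$out, c(3, 1), c(2, 1))
  wantp <- oracle_maxpool2d(array(f2$out[1, , , ], dim(f2$out)[2:4]),
                            c(3, 1), c(2, 1))
  expect_lt(max(abs(array(p2$out[1, , , ], dim(p2$out)[2:4]) - wantp)), 1e-12)
})

test_that("branch shape chains emit the documented feature counts", {
  cfg <- model_config()
  params <- init_model_params(cfg, seed = 2)
  beat <- make_beat(beat_morphology(), 235)
  pf <- periodic_branch(beat, params)
  expect_length(pf, 128)
  expect_true(all(pf >= 0))          # post-ReLU, post-max-pool

  W <- do.call(rbind, replicate(5, list(beat)))
  rf <- rhythm_branch(W, params)
  expect_length(rf, 128)
  expect_true(all(rf >= 0))

  expect_equal(feature_length(cfg), 320)

  # zero input with zero biases gives zero features
  pz <- init_model_params(cfg, zero = TRUE)
  expect_true(all(periodic_branch(rep(0, 235), pz) == 0))
  expect_true(all(rhythm_branch(matrix(0, 5, 235), pz) == 0))
  expect_error(periodic_branch(rep(0, 100), params), "length")
})

test_that("periodic branch composes its four stages like the loop oracle", {
  cfg <- model_config()
  params <- init_model_params(cfg, seed = 6)
  set.seed(61)
  beat <- runif(235)
  s1 <- oracle_conv1d(matrix(beat, ncol = 1), params$pK1, 5, params$pb1)
  s1 <- pmax(s1, 0)
  s2 <- oracle_maxpool1d(s1, 3, 2)
  s3 <- pmax(oracle_conv1d(s2, params$pK2, 5, params$pb2), 0)
  s4 <- oracle_maxpool1d(s3, 3, 1)
  expect_equal(dim(s1), c(46, 32))
  expect_equal(dim(s2), c(22, 32))
  expect_equal(dim(s3), c(4, 64))
  expect_equal(dim(s4), c(2, 64))
  expect_lt(max(abs(periodic_branch(beat, params) - as.numeric(s4))), 1e-8)
})

test_that("rhythm branch composes its four stages like the loop oracle", {
  cfg <- model_config()
  params <- init_model_params(cfg, seed = 7)
  set.seed(62)
  W <- matrix(runif(5 * 235), 5, 235)
  Xmap <- array(t(W), c(235, 5, 1))        # time x beat map
  s1 <- oracle_conv2d(Xmap, params$rK1, c(5, 1), params$rb1)
  s1 <- pmax(s1, 0)
  s2 <- oracle_maxpool2d(s1, c(3, 1), c(2, 1))
  s3 <- pmax(oracle_conv2d(s2, params$rK2, c(5, 3), params$rb2), 0)
  s4 <- oracle_maxpool2d(s3, c(3, 1), c(1, 1))
  expect_equal(dim(s1), c(46, 3, 32))
  expect_equal(dim(s2), c(22, 3, 32))
  expect_equal(dim(s3), c(4, 1, 64))
  expect_equal(dim(s4), c(2, 1, 64))
  expect_lt(max(abs(rhythm_branch(W, params) - as.numeric(s4))), 1e-8)

  # five identical beats: regression against a frozen seeded value
  Wsame <- matrix(rep(make_beat(beat_morphology(), 235), 5), 5, 235,
                  byrow = TRUE)
  rf <- rhythm_branch(Wsame, init_model_params(model_config(), seed = 1))
  expect_equal(length(rf), 128)
  expect_true(all(is.finite(rf)))
})

test_that("inference head and softmax have their closed forms", {
  cfg <- model_config()
  pz <- init_model_params(cfg, zero = TRUE)
  pred <- inference_head(rep(0.3, 320), pz)
  expect_equal(pred$probs, c(0.5, 0.5))

  expect_equal(softmax(c(3, 3)), c(0.5, 0.5))
  expect_equal(softmax(c(7, 7)), softmax(c(0, 0)))  # shift invariance
  expect_equal(softmax(c(2, 0)), c(exp(2) / (exp(2) + 1), 1 / (exp(2) + 1)),
               tolerance = 1e-12)
  z <- matrix(rnorm(20), 10, 2)
  expect_equal(rowSums(softmax(z)), rep(1, 10), tolerance = 1e-12)
})

test_that("cross-entropy evaluates its closed forms and rejects bad labels", {
  expect_equal(cross_entropy(c(0, 1), rbind(c(1, 0), c(0, 1))), 0,
               tolerance = 1e-10)
  Y <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(cross_entropy(Y, matrix(0.5, 3, 2)), log(2))
  expect_equal(cross_entropy(rbind(c(1, 0), c(0, 1)),
                             rbind(c(0.9, 0.1), c(0.2, 0.8))),
               -(log(0.9) + log(0.8)) / 2)
  expect_error(cross_entropy(rbind(c(1, 1)), rbind(c(0.5, 0.5))), "one-hot")
})

test_that("full forward pass is deterministic in eval mode with sane outputs", {
  cfg <- model_config()
  params <- init_model_params(cfg, seed = 10)
  W <- matrix(runif(5 * 235), 5, 235)
  a <- classify_window(W, params)
  b <- classify_window(W, params)
  expect_identical(a, b)
  expect_equal(sum(a$probs), 1, tolerance = 1e-12)

  pz <- init_model_params(cfg, zero = TRUE)
  expect_equal(classify_window(W, pz)$probs, c(0.5, 0.5))
})

test_that("the default model's parameter count matches the closed form", {
  cfg <- model_config()
  closed <- cell_param_count(32, 235) + cell_param_count(32, 32) +
    (7 * 1 * 32 + 32) + (5 * 32 * 64 + 64) +
    (7 * 3 * 1 * 32 + 32) + (5 * 3 * 32 * 64 + 64) +
    (320 * 32 + 32) + (32 * 2 + 2)
  expect_equal(model_param_count(cfg), closed)
  # and the actual parameter arrays agree with the count
  params <- init_model_params(cfg, seed = 1)
  n_actual <- sum(vapply(pwcnet:::param_paths(), function(p)
    length(pwcnet:::get_path(params, p)), 0))
  expect_equal(n_actual, model_param_count(cfg))
})
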