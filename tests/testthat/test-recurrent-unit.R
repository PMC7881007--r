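test_that("closed-form cell behaviour: zero parameters and saturated gate", {
  p <- cell_params(4, 3, zero = TRUE)
  c0 <- c(0.2, -0.4, 0.8, 0)
  st <- cell_step(p, c(1, 2, 3), list(c = c0, h = rep(0, 4)))
  expect_equal(as.numeric(st$gates$f), rep(0.5, 4))
  expect_equal(as.numeric(st$gates$c_tilde), rep(0, 4))
  expect_equal(as.numeric(st$state$c), 0.5 * c0)
  expect_equal(as.numeric(st$state$h), tanh(0.5 * c0))

  # saturating forget gate carries the state unchanged
  p$b_f[] <- 20
  st2 <- cell_step(p, c(1, 2, 3), list(c = c0, h = rep(0, 4)))
  expect_equal(as.numeric(st2$state$c), c0, tolerance = 1e-7)
})

test_that("vectorised cell_step matches the independent scalar oracle", {
  set.seed(101)
  worst <- 0
  for (rep in 1:100) {
    h <- sample(1:5, 1); x <- sample(1:6, 1)
    p <- rand_cell(h, x, scale = 1)
    h_prev <- runif(h, -0.9, 0.9)
    c_prev <- runif(h, -1, 1)
    x_t <- runif(x, -2, 2)
    got <- cell_step(p, x_t, list(c = c_prev, h = h_prev))
    want <- oracle_cell_step(p$W_fh, p$W_fx, p$b_f, p$W_ch, p$W_cx, p$b_c,
                             h_prev, c_prev, x_t)
    worst <- max(worst, max(abs(as.numeric(got$state$c) - want$c)),
                 max(abs(as.numeric(got$state$h) - want$h)))
  }
  expect_lte(worst, 1e-10)

  # the documented scalar example
  p <- cell_params(1, 1, zero = TRUE)
  p$W_fh[] <- 0.5; p$W_fx[] <- -0.3; p$b_f[] <- 0.1
  p$W_ch[] <- 0.2; p$W_cx[] <- 0.4
  got <- cell_step(p, 1.0, list(c = 0.8, h = 0.6))
  want <- oracle_cell_step(p$W_fh, p$W_fx, p$b_f, p$W_ch, p$W_cx, p$b_c,
                           0.6, 0.8, 1.0)
  expect_equal(as.numeric(got$state$h), want$h, tolerance = 1e-12)
})

test_that("run_sequence chains steps from the zero state", {
  p <- cell_params(2, 3, seed = 8)
  x1 <- matrix(runif(3), 1)
  one <- run_sequence(p, x1)
  step <- cell_step(p, x1[1, ], cell_state(2))
  expect_equal(one$h_seq[1, ], as.numeric(step$state$h))

  set.seed(77)
  X <- matrix(runif(9, -1, 1), 3, 3)
  got <- run_sequence(p, X)
  want <- oracle_run_sequence(p, X)
  expect_equal(got$h_seq, want$h_seq, tolerance = 1e-10)
  expect_equal(as.numeric(got$final$c), want$c_final, tolerance = 1e-10)

  pz <- cell_params(2, 3, zero = TRUE)
  gz <- run_sequence(pz, matrix(0, 4, 3))
  expect_true(all(gz$h_seq == 0))
  expect_error(run_sequence(p, matrix(numeric(0), 0, 3)), "empty")
})

test_that("state update is a convex combination and outputs stay bounded", {
  set.seed(55)
  p <- rand_cell(8, 6, scale = 2)
  ok <- TRUE
  for (rep in 1:1250) {
    stress <- rep > 1000    # last draws push inputs to magnitude 1e3
    c_prev <- runif(8, -1, 1)
    h_prev <- runif(8, -0.99, 0.99)
    x_t <- runif(6, -1, 1) * (if (stress) 1e3 else 30)
    st <- cell_step(p, x_t, list(c = c_prev, h = h_prev))
    cn <- as.numeric(st$state$c)
    ctil <- as.numeric(st$gates$c_tilde)
    lo <- pmin(c_prev, ctil) - 1e-12
    hi <- pmax(c_prev, ctil) + 1e-12
    ok <- ok && all(cn >= lo & cn <= hi) &&
      all(abs(as.numeric(st$state$h)) < 1) &&
      all(st$gates$f >= 0 & st$gates$f <= 1)
    # the gate is strictly open wherever its pre-activation has not
    # saturated past double precision
    open <- abs(st$gates$net_f) < 30
    ok <- ok && all(st$gates$f[open] > 0 & st$gates$f[open] < 1)
  }
  expect_true(ok)
})

test_that("the unit has exactly half the parameters of an LSTM cell", {
  for (hx in list(c(8, 16), c(32, 235), c(64, 100))) {
    expect_equal(cell_param_count(hx[1], hx[2]) / lstm_param_count(hx[1], hx[2]),
                 0.5)
  }
  expect_equal(cell_param_count(32, 235), 2 * 32 * (32 + 235 + 1))
  expect_equal(cell_param_count(32, 235), 17152)
  p <- cell_params(3, 7)
  n_actual <- sum(lengths(lapply(
    p[c("W_fh", "W_fx", "b_f", "W_ch", "W_cx", "b_c")], as.numeric)))
  expect_equal(n_actual, cell_param_count(3, 7))
})

test_that("bernoulli mask keeps, kills and concentrates as specified", {
  H <- matrix(runif(40), 5, 8)
  expect_equal(bernoulli_mask(H, 1, training = TRUE), H, ignore_attr = TRUE)
  expect_true(all(bernoulli_mask(H, 0, training = TRUE) == 0))
  expect_equal(bernoulli_mask(H, 0.3, training = FALSE), H)
  expect_error(bernoulli_mask(H, 1.4), "probability")

  big <- matrix(1, 100, 100)
  m <- bernoulli_mask(big, 0.5, seed = 5, training = TRUE)
  frac <- mean(attr(m, "mask"))
  expect_lte(abs(frac - 0.5), 0.02)
  # inverted scaling preserves the expected magnitude
  expect_equal(mean(m), 1, tolerance = 0.05)
})

test_that("bidirectional layer composes two runs with reversal", {
  p_f <- cell_params(2, 3, seed = 1)
  p_r <- cell_params(2, 2, seed = 2)
  set.seed(31)
  X <- matrix(runif(9, -1, 1), 3, 3)

  feat <- bidirectional_layer(p_f, p_r, X, p = 1, training = TRUE)
  # from-scratch oracle: forward pass, reverse the outputs, second pass
  fwd <- oracle_run_sequence(p_f, X)
  rev_in <- fwd$h_seq[3:1, , drop = FALSE]
  bwd <- oracle_run_sequence(p_r, rev_in)
  expect_equal(as.numeric(feat), c(fwd$h_final, bwd$h_final), tolerance = 1e-10)
  expect_length(as.numeric(feat), 4)

  # N = 1, p = 1: the reverse unit consumes exactly the single forward output
  f1 <- bidirectional_layer(p_f, p_r, X[1, , drop = FALSE], p = 1, training = TRUE)
  s1 <- oracle_run_sequence(p_f, X[1, , drop = FALSE])
  s2 <- oracle_run_sequence(p_r, matrix(s1$h_final, 1))
  expect_equal(as.numeric(f1), c(s1$h_final, s2$h_final), tolerance = 1e-10)

  # all-zero parameters give an all-zero feature
  z <- bidirectional_layer(cell_params(2, 3, zero = TRUE),
                           cell_params(2, 2, zero = TRUE), X)
  expect_true(all(as.numeric(z) == 0))

  # default-size feature has length 2h = 64
  pf <- cell_params(32, 235, seed = 3)
  pr <- cell_params(32, 32, seed = 4)
  W <- matrix(runif(5 * 235), 5, 235)
  expect_length(as.numeric(bidirectional_layer(pf, pr, W)), 64)
})
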