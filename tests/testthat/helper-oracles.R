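# Independent oracles, written as plain scalar loops with no code shared
# with the package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar transcription of the unit equations: gate, candidate, convex
# update, tanh output — element by element
oracle_cell_step <- function(W_fh, W_fx, b_f, W_ch, W_cx, b_c,
                             h_prev, c_prev, x_t) {
  h <- length(b_f)
  c_new <- numeric(h); h_new <- numeric(h)
  for (i in seq_len(h)) {
    net_f <- b_f[i]
    for (j in seq_along(h_prev)) net_f <- net_f + W_fh[i, j] * h_prev[j]
    for (j in seq_along(x_t)) net_f <- net_f + W_fx[i, j] * x_t[j]
    f <- 1 / (1 + exp(-net_f))
    net_c <- b_c[i]
    for (j in seq_along(h_prev)) net_c <- net_c + W_ch[i, j] * h_prev[j]
    for (j in seq_along(x_t)) net_c <- net_c + W_cx[i, j] * x_t[j]
    ctil <- tanh(net_c)
    c_new[i] <- f * c_prev[i] + (1 - f) * ctil
    h_new[i] <- tanh(c_new[i])
  }
  list(c = c_new, h = h_new)
}

oracle_run_sequence <- function(p, inputs) {
  h_prev <- numeric(p$hidden_size); c_prev <- numeric(p$hidden_size)
  H <- matrix(0, nrow(inputs), p$hidden_size)
  for (t in seq_len(nrow(inputs))) {
    st <- oracle_cell_step(p$W_fh, p$W_fx, p$b_f, p$W_ch, p$W_cx, p$b_c,
                           h_prev, c_prev, inputs[t, ])
    h_prev <- st$h; c_prev <- st$c
    H[t, ] <- st$h
  }
  list(h_seq = H, h_final = h_prev, c_final = c_prev)
}

# naive strided valid cross-correlation, double loop over output positions
# and taps
oracle_conv1d <- function(x, kernel, stride, bias) {
  # x: L x Cin; kernel: k x Cin x Cout
  L <- nrow(x); k <- dim(kernel)[1]
  Cin <- dim(kernel)[2]; Cout <- dim(kernel)[3]
  Lout <- (L - k) %/% stride + 1
  out <- matrix(0, Lout, Cout)
  for (co in seq_len(Cout)) for (j in seq_len(Lout)) {
    acc <- bias[co]
    for (a in seq_len(k)) for (ci in seq_len(Cin)) {
      acc <- acc + x[(j - 1) * stride + a, ci] * kernel[a, ci, co]
    }
    out[j, co] <- acc
  }
  out
}

oracle_maxpool1d <- function(x, size, stride) {
  L <- nrow(x); C <- ncol(x)
  Lout <- (L - size) %/% stride + 1
  out <- matrix(0, Lout, C)
  for (cc in seq_len(C)) for (j in seq_len(Lout)) {
    out[j, cc] <- max(x[(j - 1) * stride + seq_len(size), cc])
  }
  out
}

oracle_conv2d <- function(x, kernel, stride, bias) {
  # x: H x W x Cin; kernel: kh x kw x Cin x Cout; stride: c(sh, sw)
  H <- dim(x)[1]; W <- dim(x)[2]
  kh <- dim(kernel)[1]; kw <- dim(kernel)[2]
  Cin <- dim(kernel)[3]; Cout <- dim(kernel)[4]
  Hout <- (H - kh) %/% stride[1] + 1
  Wout <- (W - kw) %/% stride[2] + 1
  out <- array(0, c(Hout, Wout, Cout))
  for (co in seq_len(Cout)) for (u in seq_len(Hout)) for (v in seq_len(Wout)) {
    acc <- bias[co]
    for (a in seq_len(kh)) for (b in seq_len(kw)) for (ci in seq_len(Cin)) {
      acc <- acc + x[(u - 1) * stride[1] + a, (v - 1) * stride[2] + b, ci] *
        kernel[a, b, ci, co]
    }
    out[u, v, co] <- acc
  }
  out
}

oracle_maxpool2d <- function(x, size, stride) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  Hout <- (H - size[1]) %/% stride[1] + 1
  Wout <- (W - size[2]) %/% stride[2] + 1
  out <- array(0, c(Hout, Wout, C))
  for (cc in seq_len(C)) for (u in seq_len(Hout)) for (v in seq_len(Wout)) {
    out[u, v, cc] <- max(x[(u - 1) * stride[1] + seq_len(size[1]),
                           (v - 1) * stride[2] + seq_len(size[2]), cc])
  }
  out
}

# brute-force local-extremum scan (strict neighbours)
oracle_local_maxima <- function(x) {
  which(vapply(seq_along(x), function(i) {
    i > 1 && i < length(x) && x[i] > x[i - 1] && x[i] > x[i + 1]
  }, TRUE))
}

rand_cell <- function(h, x, scale = 0.5) {
  p <- cell_params(h, x, zero = TRUE)
  p$W_fh[] <- runif(h * h, -scale, scale)
  p$W_fx[] <- runif(h * x, -scale, scale)
  p$b_f[] <- runif(h, -scale, scale)
  p$W_ch[] <- runif(h * h, -scale, scale)
  p$W_cx[] <- runif(h * x, -scale, scale)
  p$b_c[] <- runif(h, -scale, scale)
  p
}
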