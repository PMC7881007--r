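#' Parameters of the small-parameter recurrent unit
#'
#' The unit has a single forgetting gate and a candidate-state block, so its
#' parameter count is `2 * h * (h + x + 1)` — exactly half that of an LSTM
#' cell (four gate blocks) at the same sizes. Weights initialise uniform in
#' `+/- 1/sqrt(h)`; biases at zero.
#'
#' @param hidden_size hidden width `h` (default 32).
#' @param input_size input width `x` (default 235, one resampled beat).
#' @param seed optional seed for reproducible initialisation.
#' @param zero initialise all blocks to zero (for tests / closed-form cases).
#' @return object of class `cell_params`: list of `W_fh` (h x h), `W_fx`
#'   (h x x), `b_f`, `W_ch`, `W_cx`, `b_c`.
#' @export
cell_params <- function(hidden_size = 32, input_size = 235, seed = NULL,
                        zero = FALSE) {
  h <- as.integer(hidden_size); x <- as.integer(input_size)
  if (h < 1 || x < 1) abort("hidden_size and input_size must be positive")
  mk <- function(r, c) {
    if (zero) matrix(0, r, c)
    else matrix(runif(r * c, -1 / sqrt(h), 1 / sqrt(h)), r, c)
  }
  with_seed_if(seed, structure(list(
    W_fh = mk(h, h), W_fx = mk(h, x), b_f = numeric(h),
    W_ch = mk(h, h), W_cx = mk(h, x), b_c = numeric(h),
    hidden_size = h, input_size = x
  ), class = "cell_params"))
}

#' Parameter counts of the unit and of an LSTM cell
#'
#' @param hidden_size,input_size layer sizes.
#' @return integer count.
#' @export
cell_param_count <- function(hidden_size, input_size) {
  2L * as.integer(hidden_size) *
    (as.integer(hidden_size) + as.integer(input_size) + 1L)
}

#' @rdname cell_param_count
#' @export
lstm_param_count <- function(hidden_size, input_size) {
  4L * as.integer(hidden_size) *
    (as.integer(hidden_size) + as.integer(input_size) + 1L)
}

#' Zero initial state
#'
#' @param hidden_size hidden width.
#' @param batch number of rows (default 1).
#' @return list with matrices `c` and `h` of dim `batch x hidden_size`.
#' @export
cell_state <- function(hidden_size, batch = 1) {
  list(c = matrix(0, batch, hidden_size), h = matrix(0, batch, hidden_size))
}

as_batch <- function(v, width) {
  if (is.matrix(v)) v else matrix(v, 1, width)
}

#' One step of the recurrent unit
#'
#' Computes the forgetting gate `f = sigmoid(W_fh h + W_fx x + b_f)`, the
#' candidate state `c~ = tanh(W_ch h + W_cx x + b_c)`, the convex state
#' update `c_t = f * c_{t-1} + (1 - f) * c~`, and the output
#' `h_t = tanh(c_t)`. The single gate both forgets old state and admits new
#' state, which halves the parameters relative to an LSTM while preserving
#' the long-term-dependence mechanism. Inputs may be a single vector or a
#' batch matrix (rows = instances).
#'
#' @param params a [cell_params()].
#' @param x_t input, length-`x` vector or `batch x x` matrix.
#' @param prev previous state from [cell_state()] or an earlier step.
#' @return list with `state` (fields `c`, `h`) and `gates` (fields `net_f`,
#'   `f`, `net_c`, `c_tilde`), all `batch x h` matrices.
#' @export
cell_step <- function(params, x_t, prev) {
  h <- params$hidden_size
  X <- as_batch(x_t, params$input_size)
  if (ncol(X) != params$input_size) abort("x_t width does not match input_size")
  Hp <- as_batch(prev$h, h); Cp <- as_batch(prev$c, h)
  if (ncol(Hp) != h || nrow(Hp) != nrow(X))
    abort("state dimensions do not match params/batch")
  bf <- matrix(params$b_f, nrow(X), h, byrow = TRUE)
  bc <- matrix(params$b_c, nrow(X), h, byrow = TRUE)
  net_f <- Hp %*% t(params$W_fh) + X %*% t(params$W_fx) + bf
  f <- sigmoid(net_f)
  net_c <- Hp %*% t(params$W_ch) + X %*% t(params$W_cx) + bc
  c_tilde <- tanh(net_c)
  C <- f * Cp + (1 - f) * c_tilde
  list(state = list(c = C, h = tanh(C)),
       gates = list(net_f = net_f, f = f, net_c = net_c, c_tilde = c_tilde))
}

#' Run the unit over a beat sequence
#'
#' Applies [cell_step()] left-to-right from `init` (zero state by default)
#' and emits every hidden output.
#'
#' @param params a [cell_params()].
#' @param inputs `N x x` matrix (one row per beat) or `batch x N x x` array.
#' @param init initial state (default zero).
#' @return list with `h_seq` (`N x h` matrix, or `batch x N x h` array for
#'   array input), `final` state, and `cache` for backpropagation.
#' @export
run_sequence <- function(params, inputs, init = NULL) {
  batched <- length(dim(inputs)) == 3
  if (!batched) {
    if (is.null(dim(inputs))) inputs <- matrix(inputs, 1)
    inputs <- array(inputs, c(1, nrow(inputs), ncol(inputs)))
  }
  B <- dim(inputs)[1]; N <- dim(inputs)[2]
  if (N < 1) abort("empty sequence")
  h <- params$hidden_size
  st <- init %||% cell_state(h, B)
  st$c <- as_batch(st$c, h); st$h <- as_batch(st$h, h)
  if (nrow(st$c) == 1 && B > 1) {
    st$c <- st$c[rep(1, B), , drop = FALSE]
    st$h <- st$h[rep(1, B), , drop = FALSE]
  }
  H <- array(0, c(B, N, h))
  cache <- vector("list", N)
  for (t in seq_len(N)) {
    Xt <- matrix(inputs[, t, ], B)
    step <- cell_step(params, Xt, st)
    cache[[t]] <- list(Xt = Xt, Hp = st$h, Cp = st$c,
                       f = step$gates$f, c_tilde = step$gates$c_tilde,
                       C = step$state$c)
    st <- step$state
    H[, t, ] <- st$h
  }
  h_seq <- if (batched) H else matrix(H[1, , ], N, h)
  list(h_seq = h_seq, final = st, cache = cache)
}

zero_grads_cell <- function(params) {
  list(W_fh = params$W_fh * 0, W_fx = params$W_fx * 0,
       b_f = numeric(params$hidden_size),
       W_ch = params$W_ch * 0, W_cx = params$W_cx * 0,
       b_c = numeric(params$hidden_size))
}

# backpropagation through time for run_sequence.
# d_hseq: B x N x h upstream gradients on every emitted h_t (may be zeros);
# d_hfinal/d_cfinal: extra gradient on the final state. Returns parameter
# gradients and d_inputs (B x N x x).
rnn_backward <- function(params, cache, d_hseq, d_hfinal = NULL,
                         d_cfinal = NULL) {
  N <- length(cache)
  B <- nrow(cache[[1]]$Xt)
  h <- params$hidden_size
  g <- zero_grads_cell(params)
  dH <- if (is.null(d_hfinal)) matrix(0, B, h) else d_hfinal
  dC <- if (is.null(d_cfinal)) matrix(0, B, h) else d_cfinal
  dX <- array(0, c(B, N, params$input_size))
  for (t in rev(seq_len(N))) {
    cc <- cache[[t]]
    dHt <- dH + matrix(d_hseq[, t, ], B)
    dC <- dC + dHt * (1 - tanh(cc$C)^2)
    df <- dC * (cc$Cp - cc$c_tilde)
    dctil <- dC * (1 - cc$f)
    dCp <- dC * cc$f
    dnet_f <- df * cc$f * (1 - cc$f)
    dnet_c <- dctil * (1 - cc$c_tilde^2)
    g$W_fh <- g$W_fh + t(dnet_f) %*% cc$Hp
    g$W_fx <- g$W_fx + t(dnet_f) %*% cc$Xt
    g$b_f <- g$b_f + colSums(dnet_f)
    g$W_ch <- g$W_ch + t(dnet_c) %*% cc$Hp
    g$W_cx <- g$W_cx + t(dnet_c) %*% cc$Xt
    g$b_c <- g$b_c + colSums(dnet_c)
    dX[, t, ] <- dnet_f %*% params$W_fx + dnet_c %*% params$W_cx
    dH <- dnet_f %*% params$W_fh + dnet_c %*% params$W_ch
    dC <- dCp
  }
  list(grads = g, d_inputs = dX, d_h0 = dH, d_c0 = dC)
}

#' Bernoulli coupling mask between the forward and reverse layers
#'
#' In training mode each element of the hidden sequence is kept with
#' probability `p` and scaled by `1/p` (inverted dropout), so evaluation mode
#' is the identity. `p = 0` zeroes the sequence.
#'
#' @param h_seq `N x h` matrix (or batch array).
#' @param p keep probability in `[0, 1]`.
#' @param seed optional seed for the mask draw.
#' @param training logical; `FALSE` returns `h_seq` unchanged.
#' @return masked sequence, with the 0/1 mask as attribute `"mask"` when
#'   training.
#' @export
bernoulli_mask <- function(h_seq, p, seed = NULL, training = TRUE) {
  check_prob(p)
  if (!training) return(h_seq)
  if (p == 0) {
    out <- h_seq * 0
    attr(out, "mask") <- h_seq * 0
    return(out)
  }
  m <- with_seed_if(seed, array(rbinom(length(h_seq), 1, p), dim = dim(h_seq) %||% length(h_seq)))
  out <- h_seq * m / p
  attr(out, "mask") <- m
  out
}

#' Bidirectional recursive layer
#'
#' Runs the forward unit over the beats in time order, passes its full hidden
#' sequence through [bernoulli_mask()], feeds the masked sequence to the
#' reverse unit in reversed time order, and returns the concatenation of the
#' two final hidden states (length `2h`, 64 under defaults) as the
#' long-term-memory feature of the window.
#'
#' @param params_fwd,params_rev [cell_params()]; the reverse unit's
#'   `input_size` must equal the forward unit's `hidden_size`.
#' @param window `N x x` matrix of beats (or `batch x N x x` array).
#' @param p keep probability of the coupling mask.
#' @param training logical; mask active only when `TRUE`.
#' @param seed optional seed for the mask.
#' @return feature vector of length `2h` (or `batch x 2h` matrix), with the
#'   full cache as attribute `"cache"`.
#' @export
bidirectional_layer <- function(params_fwd, params_rev, window, p = 0.5,
                                training = FALSE, seed = NULL) {
  batched <- length(dim(window)) == 3
  fwd <- run_sequence(params_fwd, window)
  Hf <- fwd$h_seq
  if (!batched) Hf <- array(Hf, c(1, nrow(Hf), ncol(Hf)))
  masked <- bernoulli_mask(Hf, p, seed = seed, training = training)
  N <- dim(masked)[2]
  rev_in <- masked[, rev(seq_len(N)), , drop = FALSE]
  bwd <- run_sequence(params_rev, rev_in)
  feat <- cbind(fwd$final$h, bwd$final$h)
  out <- if (batched) feat else as.numeric(feat)
  attr(out, "cache") <- list(fwd = fwd, bwd = bwd,
                             mask = attr(masked, "mask"), p = p,
                             training = training, N = N)
  out
}

# backward through bidirectional_layer given d_feat (B x 2h): returns grads
# for both units (input gradients to the beats are not needed upstream).
bidir_backward <- function(params_fwd, params_rev, cache, d_feat) {
  h <- params_fwd$hidden_size
  B <- nrow(d_feat)
  N <- cache$N
  d_hf_final <- d_feat[, seq_len(h), drop = FALSE]
  d_hr_final <- d_feat[, h + seq_len(h), drop = FALSE]
  zero_rev <- array(0, c(B, N, h))
  bk_rev <- rnn_backward(params_rev, cache$bwd$cache, zero_rev,
                         d_hfinal = d_hr_final)
  # reverse-layer input gradients map back to the masked forward outputs
  d_masked <- bk_rev$d_inputs[, rev(seq_len(N)), , drop = FALSE]
  if (cache$training) {
    m <- cache$mask
    d_masked <- if (cache$p > 0) d_masked * m / cache$p else d_masked * 0
  }
  bk_fwd <- rnn_backward(params_fwd, cache$fwd$cache, d_masked,
                         d_hfinal = d_hf_final)
  list(fwd = bk_fwd$grads, rev = bk_rev$grads)
}
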