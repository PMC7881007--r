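#' Model configuration
#'
#' Defaults give the reference architecture: beat length 235;
#' 32 hidden recurrent nodes, bidirectional, coupling dropout keep 0.5;
#' periodic branch conv(7, stride 5, 32 kernels) + pool(3, 2) then
#' conv(5, stride 5, 64) + pool(3, 1); rhythm branch conv(7x3, stride 5x1,
#' 32) + pool(3x1, 2x1) then conv(5x3, stride 5x3, 64) + pool(3x1, 1x1);
#' inference head FC(features -> 32) + ReLU then FC(32 -> 2) + softmax;
#' batch size 64; Adam.
#'
#' @param unit_cycles beats per window `N` (default 5).
#' @param cycle_length samples per beat (default 235).
#' @param hidden_nodes recurrent hidden width (default 32).
#' @param dropout_keep keep probability of the Bernoulli coupling mask.
#' @param periodic_mode `"average"` applies the periodic branch to every beat
#'   with shared weights and averages the features; `"center"` uses the
#'   middle beat only.
#' @param batch_size minibatch size for training.
#' @return object of class `model_config`.
#' @export
model_config <- function(unit_cycles = 5, cycle_length = 235,
                         hidden_nodes = 32, dropout_keep = 0.5,
                         periodic_mode = c("average", "center"),
                         batch_size = 64) {
  periodic_mode <- match.arg(periodic_mode)
  structure(list(
    unit_cycles = as.integer(unit_cycles),
    cycle_length = as.integer(cycle_length),
    hidden_nodes = as.integer(hidden_nodes),
    dropout_keep = dropout_keep,
    periodic_mode = periodic_mode,
    batch_size = as.integer(batch_size),
    periodic_conv = list(list(k = 7L, s = 5L, n = 32L),
                         list(k = 5L, s = 5L, n = 64L)),
    periodic_pool = list(list(size = 3L, s = 2L), list(size = 3L, s = 1L)),
    rhythm_conv = list(list(k = c(7L, 3L), s = c(5L, 1L), n = 32L),
                       list(k = c(5L, 3L), s = c(5L, 3L), n = 64L)),
    rhythm_pool = list(list(size = c(3L, 1L), s = c(2L, 1L)),
                       list(size = c(3L, 1L), s = c(1L, 1L))),
    fc_hidden = 32L, n_classes = 2L
  ), class = "model_config")
}

periodic_feature_len <- function(cfg) {
  L <- cfg$cycle_length
  for (i in 1:2) {
    L <- conv_out_len(L, cfg$periodic_conv[[i]]$k, cfg$periodic_conv[[i]]$s)
    L <- conv_out_len(L, cfg$periodic_pool[[i]]$size, cfg$periodic_pool[[i]]$s)
  }
  L * cfg$periodic_conv[[2]]$n
}

rhythm_feature_len <- function(cfg) {
  H <- cfg$cycle_length; W <- cfg$unit_cycles
  for (i in 1:2) {
    k <- cfg$rhythm_conv[[i]]$k; s <- cfg$rhythm_conv[[i]]$s
    W <- max(W, k[2])   # beat axis is edge-padded up to the kernel width
    H <- conv_out_len(H, k[1], s[1]); W <- conv_out_len(W, k[2], s[2])
    p <- cfg$rhythm_pool[[i]]
    H <- conv_out_len(H, p$size[1], p$s[1]); W <- conv_out_len(W, p$size[2], p$s[2])
  }
  H * W * cfg$rhythm_conv[[2]]$n
}

# edge-replication padding along the beat axis, used when a window holds
# fewer beats than the kernel is wide (N < 3 at conv 1; N < 5 leaves width
# < 3 at conv 2). The default N = 5 chain never pads.
pad_beat_axis <- function(X, kw) {
  W <- dim(X)[3]
  if (W >= kw) return(list(x = X, orig = W))
  idx <- c(seq_len(W), rep(W, kw - W))
  list(x = X[, , idx, , drop = FALSE], orig = W)
}

fold_beat_axis <- function(dX, orig) {
  W <- dim(dX)[3]
  if (W == orig) return(dX)
  out <- dX[, , seq_len(orig), , drop = FALSE]
  for (j in (orig + 1):W)
    out[, , orig, ] <- out[, , orig, , drop = FALSE] +
      dX[, , j, , drop = FALSE]
  out
}

#' Combined feature length of the three branches
#'
#' @param cfg a [model_config()].
#' @return integer: recursive (2h) + periodic + rhythm feature counts.
#' @export
feature_length <- function(cfg = model_config()) {
  2L * cfg$hidden_nodes + periodic_feature_len(cfg) + rhythm_feature_len(cfg)
}

uinit <- function(dims, fan_in, zero = FALSE) {
  if (zero) return(array(0, dims))
  array(runif(prod(dims), -1 / sqrt(fan_in), 1 / sqrt(fan_in)), dims)
}

#' Initialise all model parameters
#'
#' Recurrent blocks are uniform in `+/- 1/sqrt(h)`; convolution and dense
#' blocks uniform in `+/- 1/sqrt(fan_in)`; biases zero.
#'
#' @param cfg a [model_config()].
#' @param seed optional seed.
#' @param zero all-zero parameters (for closed-form tests).
#' @return object of class `model_params`: named list of parameter arrays.
#' @export
init_model_params <- function(cfg = model_config(), seed = NULL, zero = FALSE) {
  with_seed_if(seed, {
    h <- cfg$hidden_nodes
    pc <- cfg$periodic_conv; rc <- cfg$rhythm_conv
    feat <- feature_length(cfg)
    p <- list(
      cell_fwd = cell_params(h, cfg$cycle_length, zero = zero),
      cell_rev = cell_params(h, h, zero = zero),
      pK1 = uinit(c(pc[[1]]$k, 1, pc[[1]]$n), pc[[1]]$k, zero),
      pb1 = numeric(pc[[1]]$n),
      pK2 = uinit(c(pc[[2]]$k, pc[[1]]$n, pc[[2]]$n),
                  pc[[2]]$k * pc[[1]]$n, zero),
      pb2 = numeric(pc[[2]]$n),
      rK1 = uinit(c(rc[[1]]$k, 1, rc[[1]]$n), prod(rc[[1]]$k), zero),
      rb1 = numeric(rc[[1]]$n),
      rK2 = uinit(c(rc[[2]]$k, rc[[1]]$n, rc[[2]]$n),
                  prod(rc[[2]]$k) * rc[[1]]$n, zero),
      rb2 = numeric(rc[[2]]$n),
      fcW1 = uinit(c(cfg$fc_hidden, feat), feat, zero),
      fcb1 = numeric(cfg$fc_hidden),
      fcW2 = uinit(c(cfg$n_classes, cfg$fc_hidden), cfg$fc_hidden, zero),
      fcb2 = numeric(cfg$n_classes)
    )
    structure(p, class = "model_params", config = cfg)
  })
}

#' Closed-form parameter count of the default model
#'
#' Sums the two recurrent units (forward on beats, reverse on hidden
#' states), the convolution kernel banks with biases, and the two dense
#' layers.
#'
#' @param cfg a [model_config()].
#' @return integer total.
#' @export
model_param_count <- function(cfg = model_config()) {
  h <- cfg$hidden_nodes
  pc <- cfg$periodic_conv; rc <- cfg$rhythm_conv
  feat <- feature_length(cfg)
  cell_param_count(h, cfg$cycle_length) + cell_param_count(h, h) +
    (pc[[1]]$k * 1 * pc[[1]]$n + pc[[1]]$n) +
    (pc[[2]]$k * pc[[1]]$n * pc[[2]]$n + pc[[2]]$n) +
    (prod(rc[[1]]$k) * 1 * rc[[1]]$n + rc[[1]]$n) +
    (prod(rc[[2]]$k) * rc[[1]]$n * rc[[2]]$n + rc[[2]]$n) +
    (feat * cfg$fc_hidden + cfg$fc_hidden) +
    (cfg$fc_hidden * cfg$n_classes + cfg$n_classes)
}

# ---- batched branch forward/backward ---------------------------------------

periodic_forward <- function(params, X, cfg) {
  # X: (B, N, L). Shared weights over beats: fold beats into the batch.
  B <- dim(X)[1]; N <- dim(X)[2]; L <- dim(X)[3]
  if (cfg$periodic_mode == "center") {
    mid <- (N + 1L) %/% 2L
    Xb <- array(X[, mid, ], c(B, 1L, L))
    N_eff <- 1L
  } else {
    Xb <- X
    N_eff <- N
  }
  Xf <- array(aperm(Xb, c(1, 2, 3)), c(B * N_eff, L, 1))
  c1 <- conv1d_forward(Xf, params$pK1, params$pb1, cfg$periodic_conv[[1]]$s)
  r1 <- relu(c1$out)
  p1 <- maxpool1d_forward(r1, cfg$periodic_pool[[1]]$size, cfg$periodic_pool[[1]]$s)
  c2 <- conv1d_forward(p1$out, params$pK2, params$pb2, cfg$periodic_conv[[2]]$s)
  r2 <- relu(c2$out)
  p2 <- maxpool1d_forward(r2, cfg$periodic_pool[[2]]$size, cfg$periodic_pool[[2]]$s)
  Ff <- matrix(p2$out, B * N_eff)              # (B*N, feat)
  feat_len <- ncol(Ff)
  Fb <- array(Ff, c(B, N_eff, feat_len))
  feat <- matrix(0, B, feat_len)
  for (t in seq_len(N_eff)) feat <- feat + matrix(Fb[, t, ], B)
  feat <- feat / N_eff
  list(out = feat,
       cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                    B = B, N_eff = N_eff, feat_len = feat_len,
                    out_dim2 = dim(p2$out)))
}

periodic_backward <- function(params, cache, dFeat) {
  B <- cache$B; N_eff <- cache$N_eff
  dFb <- array(0, c(B, N_eff, cache$feat_len))
  for (t in seq_len(N_eff)) dFb[, t, ] <- dFeat / N_eff
  dP2 <- array(matrix(dFb, B * N_eff), cache$out_dim2)
  dR2 <- maxpool1d_backward(cache$p2$cache, dP2)
  dC2 <- dR2 * (cache$c2$out > 0)
  b2 <- conv1d_backward(cache$c2$cache, dC2)
  dR1 <- maxpool1d_backward(cache$p1$cache, b2$dX)
  dC1 <- dR1 * (cache$c1$out > 0)
  b1 <- conv1d_backward(cache$c1$cache, dC1)
  list(dpK1 = b1$dK, dpb1 = b1$db, dpK2 = b2$dK, dpb2 = b2$db)
}

rhythm_forward <- function(params, X, cfg) {
  # X: (B, N, L) -> feature map (B, L time, N beats, 1 channel)
  B <- dim(X)[1]; N <- dim(X)[2]; L <- dim(X)[3]
  Xm <- array(aperm(X, c(1, 3, 2)), c(B, L, N, 1))
  pd1 <- pad_beat_axis(Xm, cfg$rhythm_conv[[1]]$k[2])
  c1 <- conv2d_forward(pd1$x, params$rK1, params$rb1, cfg$rhythm_conv[[1]]$s)
  r1 <- relu(c1$out)
  p1 <- maxpool2d_forward(r1, cfg$rhythm_pool[[1]]$size, cfg$rhythm_pool[[1]]$s)
  pd2 <- pad_beat_axis(p1$out, cfg$rhythm_conv[[2]]$k[2])
  c2 <- conv2d_forward(pd2$x, params$rK2, params$rb2, cfg$rhythm_conv[[2]]$s)
  r2 <- relu(c2$out)
  p2 <- maxpool2d_forward(r2, cfg$rhythm_pool[[2]]$size, cfg$rhythm_pool[[2]]$s)
  feat <- matrix(p2$out, B)
  list(out = feat, cache = list(c1 = c1, p1 = p1, c2 = c2, p2 = p2,
                                orig1 = pd1$orig, orig2 = pd2$orig,
                                out_dim2 = dim(p2$out)))
}

rhythm_backward <- function(params, cache, dFeat) {
  dP2 <- array(dFeat, cache$out_dim2)
  dR2 <- maxpool2d_backward(cache$p2$cache, dP2)
  dC2 <- dR2 * (cache$c2$out > 0)
  b2 <- conv2d_backward(cache$c2$cache, dC2)
  dP1 <- fold_beat_axis(b2$dX, cache$orig2)
  dR1 <- maxpool2d_backward(cache$p1$cache, dP1)
  dC1 <- dR1 * (cache$c1$out > 0)
  b1 <- conv2d_backward(cache$c1$cache, dC1)
  list(drK1 = b1$dK, drb1 = b1$db, drK2 = b2$dK, drb2 = b2$db)
}

#' Full model forward pass
#'
#' Runs the bidirectional recursive layer over the window's beats, the
#' periodic (1-D conv) branch on each beat with shared weights, and the
#' rhythm (2-D conv) branch on the time-by-beat map; concatenates the three
#' feature vectors and applies the two-layer inference head with softmax.
#'
#' @param params a [init_model_params()] result.
#' @param X `batch x N x 235` array of windows (a single `N x 235` matrix is
#'   promoted to batch 1).
#' @param cfg a [model_config()].
#' @param training logical: activates the Bernoulli coupling mask.
#' @param mask_seed optional seed for the mask draw.
#' @return list with `probs`, `logits` (`batch x 2`), `features`
#'   (`batch x feature_length`), and `cache` for [model_backward()].
#' @export
model_forward <- function(params, X, cfg = attr(params, "config"),
                          training = FALSE, mask_seed = NULL) {
  if (length(dim(X)) == 2) X <- array(X, c(1, dim(X)))
  B <- dim(X)[1]
  rec <- bidirectional_layer(params$cell_fwd, params$cell_rev, X,
                             p = cfg$dropout_keep, training = training,
                             seed = mask_seed)
  rec_cache <- attr(rec, "cache")
  rec <- matrix(rec, B)
  per <- periodic_forward(params, X, cfg)
  rhy <- rhythm_forward(params, X, cfg)
  feats <- cbind(rec, per$out, rhy$out)
  d1 <- dense_forward(feats, params$fcW1, params$fcb1)
  a1 <- relu(d1$out)
  d2 <- dense_forward(a1, params$fcW2, params$fcb2)
  probs <- softmax(d2$out)
  list(probs = probs, logits = d2$out, features = feats,
       cache = list(rec_cache = rec_cache, per = per, rhy = rhy,
                    d1 = d1, a1 = a1, d2 = d2,
                    n_rec = ncol(rec), n_per = ncol(per$out),
                    B = B, cfg = cfg))
}

#' Backward pass of the full model
#'
#' Given one-hot labels, backpropagates the mean softmax cross-entropy
#' through the head, the three branches and the recurrent stack.
#'
#' @param params model parameters.
#' @param fw result of [model_forward()].
#' @param Y one-hot `batch x 2` label matrix.
#' @return named list of gradients matching the structure of `params`.
#' @export
model_backward <- function(params, fw, Y) {
  cache <- fw$cache
  B <- cache$B
  dLogits <- (fw$probs - Y) / B
  b2 <- dense_backward(cache$d2$cache, dLogits)
  dA1 <- b2$dX * (cache$d1$out > 0)
  b1 <- dense_backward(cache$d1$cache, dA1)
  dFeats <- b1$dX
  n_rec <- cache$n_rec; n_per <- cache$n_per
  dRec <- dFeats[, seq_len(n_rec), drop = FALSE]
  dPer <- dFeats[, n_rec + seq_len(n_per), drop = FALSE]
  dRhy <- dFeats[, (n_rec + n_per + 1):ncol(dFeats), drop = FALSE]
  gb <- bidir_backward(params$cell_fwd, params$cell_rev, cache$rec_cache, dRec)
  gp <- periodic_backward(params, cache$per$cache, dPer)
  gr <- rhythm_backward(params, cache$rhy$cache, dRhy)
  list(cell_fwd = gb$fwd, cell_rev = gb$rev,
       pK1 = gp$dpK1, pb1 = gp$dpb1, pK2 = gp$dpK2, pb2 = gp$dpb2,
       rK1 = gr$drK1, rb1 = gr$drb1, rK2 = gr$drK2, rb2 = gr$drb2,
       fcW1 = b1$dW, fcb1 = b1$db, fcW2 = b2$dW, fcb2 = b2$db)
}

# ---- single-instance wrappers (the public branch surface) ------------------

#' Periodic feature branch on one beat
#'
#' conv(7, stride 5, 32) + ReLU, pool(3, 2), conv(5, stride 5, 64) + ReLU,
#' pool(3, 1), flatten; under defaults the shape chain is 235 -> 46 -> 22 ->
#' 4 -> 2, times 64 channels = 128 features.
#'
#' @param beat length-235 numeric vector (a `pwc_beat` works).
#' @param params model parameters (defaults to seeded fresh ones).
#' @param cfg a [model_config()].
#' @return length-128 feature vector.
#' @export
periodic_branch <- function(beat, params = NULL, cfg = model_config()) {
  if (length(beat) != cfg$cycle_length)
    abort(sprintf("beat must have length %d", cfg$cycle_length))
  params <- params %||% init_model_params(cfg, seed = 1)
  X <- array(as.numeric(beat), c(1, 1, length(beat)))
  cfg1 <- cfg; cfg1$periodic_mode <- "average"
  as.numeric(periodic_forward(params, X, cfg1)$out)
}

#' Rhythm feature branch on one window
#'
#' The `N x 235` window is treated as a 235 (time) by `N` (beat) map;
#' conv(7x3, stride 5x1, 32) + ReLU, pool(3x1, 2x1), conv(5x3, stride 5x3,
#' 64) + ReLU, pool(3x1, 1x1), flatten; under defaults (N = 5) the chain is
#' (235,5) -> (46,3) -> (22,3) -> (4,1) -> (2,1), times 64 channels = 128
#' features.
#'
#' @param window `N x 235` matrix or a `beat_window`.
#' @param params model parameters.
#' @param cfg a [model_config()].
#' @return length-128 feature vector.
#' @export
rhythm_branch <- function(window, params = NULL, cfg = model_config()) {
  if (inherits(window, "beat_window")) window <- window$beats
  params <- params %||% init_model_params(cfg, seed = 1)
  X <- array(window, c(1, dim(window)))
  as.numeric(rhythm_forward(params, X, cfg)$out)
}

#' Inference head
#'
#' FC(features -> 32) + ReLU, FC(32 -> 2), softmax.
#'
#' @param features combined feature vector (length [feature_length()]).
#' @param params model parameters.
#' @param cfg a [model_config()].
#' @return list with `logits` and `probs` (length 2, probs sum to 1).
#' @export
inference_head <- function(features, params = NULL, cfg = model_config()) {
  params <- params %||% init_model_params(cfg, seed = 1)
  if (length(features) != ncol(params$fcW1))
    abort("feature length does not match the head")
  z1 <- relu(as.numeric(params$fcW1 %*% features + params$fcb1))
  z2 <- as.numeric(params$fcW2 %*% z1 + params$fcb2)
  list(logits = z2, probs = softmax(z2))
}

#' Classify one beat window
#'
#' Convenience single-window forward pass; see [model_forward()].
#'
#' @param window `N x 235` matrix or `beat_window`.
#' @param params model parameters.
#' @param cfg a [model_config()].
#' @param training activate the coupling mask (default `FALSE`:
#'   deterministic evaluation).
#' @return list with `logits` and `probs` (length 2).
#' @export
classify_window <- function(window, params, cfg = attr(params, "config"),
                            training = FALSE) {
  if (inherits(window, "beat_window")) window <- window$beats
  fw <- model_forward(params, window, cfg, training = training)
  list(logits = as.numeric(fw$logits), probs = as.numeric(fw$probs))
}
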