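# Low-level network layers: valid (no-padding) strided convolutions, max
# pooling and dense layers, each with an explicit backward pass. Batched
# layouts: 1-D data (B, L, C); 2-D data (B, H, W, C). Kernels: (k, Cin, Cout)
# and (kh, kw, Cin, Cout). All implemented via im2col + BLAS matmul.

conv_out_len <- function(L, k, s) (L - k) %/% s + 1L

# gather X (B, L, Cin) into M (B*Lout, k*Cin), k fastest then Cin —
# matching R's column-major flattening of a (k, Cin, Cout) kernel
im2col1d <- function(X, k, s) {
  B <- dim(X)[1]; L <- dim(X)[2]; Cin <- dim(X)[3]
  Lout <- conv_out_len(L, k, s)
  idx <- as.vector(outer(seq_len(k), (seq_len(Lout) - 1L) * s, `+`)) # k fast
  Xg <- X[, idx, , drop = FALSE]                 # (B, k*Lout, Cin)
  Xg <- array(Xg, c(B, k, Lout, Cin))
  M <- aperm(Xg, c(1, 3, 2, 4))                  # (B, Lout, k, Cin)
  dim(M) <- c(B * Lout, k * Cin)
  list(M = M, Lout = Lout)
}

conv1d_forward <- function(X, K, b, stride) {
  B <- dim(X)[1]; k <- dim(K)[1]; Cin <- dim(K)[2]; Cout <- dim(K)[3]
  if (dim(X)[3] != Cin) abort("channel mismatch in conv1d")
  if (dim(X)[2] < k) abort("input shorter than kernel")
  ic <- im2col1d(X, k, stride)
  Kmat <- matrix(K, k * Cin, Cout)
  Y <- ic$M %*% Kmat
  Y <- sweep(Y, 2, b, `+`)
  out <- array(Y, c(B, ic$Lout, Cout))
  list(out = out, cache = list(M = ic$M, X_dim = dim(X), k = k,
                               stride = stride, Lout = ic$Lout, Kmat = Kmat,
                               Cin = Cin, Cout = Cout, B = B))
}

conv1d_backward <- function(cache, dY) {
  B <- cache$B; Lout <- cache$Lout; k <- cache$k; s <- cache$stride
  Cin <- cache$Cin; Cout <- cache$Cout
  dYmat <- matrix(dY, B * Lout, Cout)
  dK <- array(t(cache$M) %*% dYmat, c(k, Cin, Cout))
  db <- colSums(dYmat)
  dM <- dYmat %*% t(cache$Kmat)               # (B*Lout, k*Cin)
  dM <- array(dM, c(B, Lout, k, Cin))
  dX <- array(0, cache$X_dim)
  for (a in seq_len(k)) {
    pos <- (seq_len(Lout) - 1L) * s + a
    dX[, pos, ] <- dX[, pos, , drop = FALSE] +
      array(dM[, , a, , drop = FALSE], c(B, Lout, Cin))
  }
  list(dX = dX, dK = dK, db = db)
}

maxpool1d_forward <- function(X, size, stride) {
  B <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  if (L < size) abort("input shorter than pooling window")
  Lout <- conv_out_len(L, size, stride)
  best <- X[, (seq_len(Lout) - 1L) * stride + 1L, , drop = FALSE]
  arg <- array(1L, c(B, Lout, C))
  for (a in 2:size) {
    cand <- X[, (seq_len(Lout) - 1L) * stride + a, , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- a
  }
  list(out = best, cache = list(arg = arg, X_dim = dim(X), size = size,
                                stride = stride, Lout = Lout))
}

maxpool1d_backward <- function(cache, dY) {
  dX <- array(0, cache$X_dim)
  Lout <- cache$Lout; s <- cache$stride
  for (a in seq_len(cache$size)) {
    pos <- (seq_len(Lout) - 1L) * s + a
    dX[, pos, ] <- dX[, pos, , drop = FALSE] + dY * (cache$arg == a)
  }
  dX
}

im2col2d <- function(X, kh, kw, sh, sw) {
  B <- dim(X)[1]; H <- dim(X)[2]; W <- dim(X)[3]; Cin <- dim(X)[4]
  Hout <- conv_out_len(H, kh, sh); Wout <- conv_out_len(W, kw, sw)
  Mw <- array(0, c(B, Hout, Wout, kh, kw, Cin))
  for (a in seq_len(kh)) for (cpos in seq_len(kw)) {
    Mw[, , , a, cpos, ] <- X[, (seq_len(Hout) - 1L) * sh + a,
                             (seq_len(Wout) - 1L) * sw + cpos, , drop = FALSE]
  }
  M <- array(Mw, c(B * Hout * Wout, kh * kw * Cin))
  list(M = M, Hout = Hout, Wout = Wout)
}

conv2d_forward <- function(X, K, b, stride) {
  kh <- dim(K)[1]; kw <- dim(K)[2]; Cin <- dim(K)[3]; Cout <- dim(K)[4]
  if (dim(X)[4] != Cin) abort("channel mismatch in conv2d")
  if (dim(X)[2] < kh || dim(X)[3] < kw) abort("input smaller than kernel")
  B <- dim(X)[1]
  ic <- im2col2d(X, kh, kw, stride[1], stride[2])
  Kmat <- matrix(K, kh * kw * Cin, Cout)
  Y <- sweep(ic$M %*% Kmat, 2, b, `+`)
  out <- array(Y, c(B, ic$Hout, ic$Wout, Cout))
  list(out = out, cache = list(M = ic$M, X_dim = dim(X), kh = kh, kw = kw,
                               stride = stride, Hout = ic$Hout,
                               Wout = ic$Wout, Kmat = Kmat, Cin = Cin,
                               Cout = Cout, B = B))
}

conv2d_backward <- function(cache, dY) {
  B <- cache$B; Hout <- cache$Hout; Wout <- cache$Wout
  kh <- cache$kh; kw <- cache$kw; Cin <- cache$Cin; Cout <- cache$Cout
  sh <- cache$stride[1]; sw <- cache$stride[2]
  dYmat <- matrix(dY, B * Hout * Wout, Cout)
  dK <- array(t(cache$M) %*% dYmat, c(kh, kw, Cin, Cout))
  db <- colSums(dYmat)
  dM <- array(dYmat %*% t(cache$Kmat), c(B, Hout, Wout, kh, kw, Cin))
  dX <- array(0, cache$X_dim)
  for (a in seq_len(kh)) for (cpos in seq_len(kw)) {
    hp <- (seq_len(Hout) - 1L) * sh + a
    wp <- (seq_len(Wout) - 1L) * sw + cpos
    dX[, hp, wp, ] <- dX[, hp, wp, , drop = FALSE] +
      array(dM[, , , a, cpos, , drop = FALSE], c(B, Hout, Wout, Cin))
  }
  list(dX = dX, dK = dK, db = db)
}

maxpool2d_forward <- function(X, size, stride) {
  B <- dim(X)[1]; H <- dim(X)[2]; W <- dim(X)[3]; C <- dim(X)[4]
  ph <- size[1]; pw <- size[2]; sh <- stride[1]; sw <- stride[2]
  if (H < ph || W < pw) abort("input smaller than pooling window")
  Hout <- conv_out_len(H, ph, sh); Wout <- conv_out_len(W, pw, sw)
  best <- NULL; arg <- NULL
  first <- TRUE
  for (a in seq_len(ph)) for (cpos in seq_len(pw)) {
    cand <- X[, (seq_len(Hout) - 1L) * sh + a,
              (seq_len(Wout) - 1L) * sw + cpos, , drop = FALSE]
    code <- (a - 1L) * pw + cpos
    if (first) {
      best <- cand; arg <- array(code, dim(cand)); first <- FALSE
    } else {
      upd <- cand > best
      best[upd] <- cand[upd]
      arg[upd] <- code
    }
  }
  list(out = best, cache = list(arg = arg, X_dim = dim(X), size = size,
                                stride = stride, Hout = Hout, Wout = Wout))
}

maxpool2d_backward <- function(cache, dY) {
  dX <- array(0, cache$X_dim)
  ph <- cache$size[1]; pw <- cache$size[2]
  sh <- cache$stride[1]; sw <- cache$stride[2]
  for (a in seq_len(ph)) for (cpos in seq_len(pw)) {
    code <- (a - 1L) * pw + cpos
    hp <- (seq_len(cache$Hout) - 1L) * sh + a
    wp <- (seq_len(cache$Wout) - 1L) * sw + cpos
    dX[, hp, wp, ] <- dX[, hp, wp, , drop = FALSE] + dY * (cache$arg == code)
  }
  dX
}

dense_forward <- function(X, W, b) {
  # X: (B, in); W: (out, in)
  Y <- X %*% t(W)
  Y <- sweep(Y, 2, b, `+`)
  list(out = Y, cache = list(X = X, W = W))
}

dense_backward <- function(cache, dY) {
  list(dX = dY %*% cache$W, dW = t(dY) %*% cache$X, db = colSums(dY))
}

#' Valid strided 1-D convolution (single instance)
#'
#' Cross-correlates a (multi-channel) series with a kernel bank, no padding,
#' plus per-output-channel bias. Output length is `(L - k) %/% s + 1`.
#'
#' @param x numeric vector (one channel) or `L x C_in` matrix.
#' @param kernel `k x C_in x C_out` array (a `k`-vector is taken as
#'   `k x 1 x 1`).
#' @param stride positive integer stride.
#' @param bias length-`C_out` bias (default zeros).
#' @param activation `"linear"` or `"relu"`.
#' @return `L_out x C_out` matrix.
#' @export
conv1d_valid <- function(x, kernel, stride = 1, bias = NULL,
                         activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.null(dim(kernel))) kernel <- array(kernel, c(length(kernel), 1, 1))
  X <- array(x, c(1, nrow(x), ncol(x)))
  Cout <- dim(kernel)[3]
  if (is.null(bias)) bias <- numeric(Cout)
  f <- conv1d_forward(X, kernel, bias, stride)
  out <- matrix(f$out[1, , ], dim(f$out)[2], Cout)
  if (activation == "relu") out <- relu(out)
  out
}

#' Valid strided 1-D max pooling (single instance)
#'
#' @param x numeric vector or `L x C` matrix.
#' @param size pooling window (default 3).
#' @param stride stride.
#' @return `L_out x C` matrix (vector input returns a vector).
#' @export
maxpool1d <- function(x, size = 3, stride = 1) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  X <- array(x, c(1, nrow(x), ncol(x)))
  f <- maxpool1d_forward(X, size, stride)
  out <- matrix(f$out[1, , ], dim(f$out)[2], ncol(x))
  if (vec) as.numeric(out) else out
}

#' Softmax over the last dimension
#'
#' @param z numeric vector or matrix of logits (rows = instances).
#' @return probabilities summing to 1 per row.
#' @export
softmax <- function(z) {
  if (is.null(dim(z))) {
    e <- exp(z - max(z))
    return(e / sum(e))
  }
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

#' Mean cross-entropy loss
#'
#' Standard cross-entropy `-(1/N) sum_i sum_j y_ij log(p_ij)` with the
#' probabilities clipped to at least `eps` before the logarithm.
#'
#' @param labels one-hot `N x M` matrix (or a 0/1 vector for two classes).
#' @param probs `N x M` matrix of predicted probabilities, rows summing to 1.
#' @param eps clipping floor (default 1e-12).
#' @return scalar loss (>= 0).
#' @export
cross_entropy <- function(labels, probs, eps = 1e-12) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1)
  if (is.null(dim(labels))) {
    if (length(labels) == nrow(probs) && all(labels %in% c(0, 1)))
      labels <- cbind(1 - labels, labels)
    else labels <- matrix(labels, 1)
  }
  if (!all(dim(labels) == dim(probs))) abort("labels/probs shape mismatch")
  if (any(rowSums(labels) != 1) || any(labels < 0))
    abort("labels must be one-hot rows")
  -mean(rowSums(labels * log(pmax(probs, eps))))
}
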