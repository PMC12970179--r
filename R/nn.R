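# Minimal dense/attention/convolution primitives (pure matrix code).
# Forward passes are deterministic functions of (input, params); all
# randomness lives in parameter initialization under an explicit seed.

.init_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(1 / max(1, nc))), nr, nc)
}

.dense <- function(x, W, b = NULL) {
  y <- x %*% t(W)
  if (!is.null(b)) y <- sweep(y, 2, b, "+")
  y
}

.softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

.layer_norm <- function(x, eps = 1e-5) {
  mu <- rowMeans(x)
  s <- sqrt(rowMeans((x - mu)^2) + eps)
  (x - mu) / s
}

.relu <- function(x) { x[x < 0] <- 0; x }

# one multi-head self-attention block; X: n_tokens x d. `key_mask` marks
# tokens excluded as keys (padding). Returns list(out, attn) where attn is
# the head-averaged n x n attention matrix.
.mha <- function(X, p, heads, key_mask = NULL) {
  d <- ncol(X); dh <- d %/% heads
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  n <- nrow(X)
  out <- matrix(0, n, d)
  attn_sum <- matrix(0, n, n)
  for (h in seq_len(heads)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    logits <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
    if (!is.null(key_mask) && any(key_mask)) logits[, key_mask] <- -1e30
    A <- .softmax_rows(logits)
    out[, idx] <- A %*% V[, idx, drop = FALSE]
    attn_sum <- attn_sum + A
  }
  list(out = out %*% p$Wo, attn = attn_sum / heads)
}

.init_transformer_layer <- function(d, ffn_mult = 2L) {
  list(Wq = .init_mat(d, d), Wk = .init_mat(d, d), Wv = .init_mat(d, d),
       Wo = .init_mat(d, d),
       W1 = .init_mat(ffn_mult * d, d), b1 = numeric(ffn_mult * d),
       W2 = .init_mat(d, ffn_mult * d), b2 = numeric(d))
}

# pre-norm transformer layer
.transformer_layer <- function(X, p, heads, key_mask = NULL) {
  a <- .mha(.layer_norm(X), p, heads, key_mask)
  X <- X + a$out
  h <- .relu(.dense(.layer_norm(X), p$W1, p$b1))
  list(out = X + .dense(h, p$W2, p$b2), attn = a$attn)
}

# 2D convolution via im2col; x: h x w x cin, W: kh x kw x cin x cout
.conv2d <- function(x, W, b, stride = 1L, pad = 0L) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  kh <- dim(W)[1]; kw <- dim(W)[2]; cout <- dim(W)[4]
  if (pad > 0L) {
    xp <- array(0, c(h + 2 * pad, w + 2 * pad, cin))
    xp[pad + seq_len(h), pad + seq_len(w), ] <- x
    x <- xp; h <- h + 2 * pad; w <- w + 2 * pad
  }
  ho <- (h - kh) %/% stride + 1L; wo <- (w - kw) %/% stride + 1L
  ys <- (seq_len(ho) - 1L) * stride
  xs <- (seq_len(wo) - 1L) * stride
  cols <- matrix(0, ho * wo, kh * kw * cin)
  cidx <- 0L
  for (ci in seq_len(cin)) for (kx in seq_len(kw)) for (ky in seq_len(kh)) {
    cidx <- cidx + 1L
    cols[, cidx] <- x[rep(ys + ky, wo) + (h * (rep(xs + kx, each = ho) - 1L)) +
                        (ci - 1L) * h * w]
  }
  Wm <- matrix(W, kh * kw * cin, cout)
  out <- cols %*% Wm
  out <- sweep(out, 2, b, "+")
  array(out, c(ho, wo, cout))
}

.avg_pool2 <- function(x) {
  h <- dim(x)[1] %/% 2L; w <- dim(x)[2] %/% 2L
  x <- x[seq_len(2 * h), seq_len(2 * w), , drop = FALSE]
  (x[seq(1, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
     x[seq(2, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
     x[seq(1, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE] +
     x[seq(2, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE]) / 4
}

# sinusoidal positional encoding, n positions x d
.sinusoid_pe <- function(n, d) {
  pos <- seq_len(n) - 1L
  i <- seq_len(d)
  freq <- 1 / (10000^(((i - 1L) %/% 2L) * 2L / d))
  ang <- outer(pos, freq)
  pe <- matrix(0, n, d)
  odd <- seq(1, d, 2); even <- seq(2, d, 2)
  pe[, odd] <- sin(ang[, odd, drop = FALSE])
  pe[, even] <- cos(ang[, even, drop = FALSE])
  pe
}
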