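# Independent, loop-based reference implementations of the attention
# operations, written directly from their defining formulas.  They share no
# code with the package internals and are deliberately slow and explicit.

sigmoid_ref <- function(x) 1 / (1 + exp(-x))

# channel attention: sigmoid(MLP(avgpool) + MLP(maxpool)) with a shared
# one-hidden-layer perceptron (ReLU after the first layer)
oracle_channel_attention <- function(x, w) {
  C <- dim(x)[3L]
  s_avg <- numeric(C); s_max <- numeric(C)
  for (c in seq_len(C)) {
    s_avg[c] <- mean(x[, , c])
    s_max[c] <- max(x[, , c])
  }
  mlp <- function(v) {
    h <- as.vector(v %*% w$W0) + w$b0
    h[h < 0] <- 0
    as.vector(h %*% w$W1) + w$b1
  }
  sigmoid_ref(mlp(s_avg) + mlp(s_max))
}

# direct 2D convolution with zero padding, kernel given as k x k x Cin
conv2d_ref <- function(planes, kern, bias = 0) {
  k <- dim(kern)[1L]; p <- (k - 1) / 2
  H <- dim(planes)[1L]; W <- dim(planes)[2L]; Cin <- dim(planes)[3L]
  out <- matrix(bias, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (ci in seq_len(Cin)) for (kw in seq_len(k)) for (kh in seq_len(k)) {
      si <- i + kh - 1 - p; sj <- j + kw - 1 - p
      if (si >= 1 && si <= H && sj >= 1 && sj <= W)
        acc <- acc + planes[si, sj, ci] * kern[kh, kw, ci]
    }
    out[i, j] <- out[i, j] + acc
  }
  out
}

# spatial attention: 7x7 convolution over the [channel-mean; channel-max]
# stack, then sigmoid
oracle_spatial_attention <- function(x, w) {
  H <- dim(x)[1L]; W <- dim(x)[2L]
  avg <- apply(x, c(1, 2), mean)
  mx <- apply(x, c(1, 2), max)
  stack <- array(c(avg, mx), c(H, W, 2L))
  kern <- array(w$W, c(7L, 7L, 2L))   # rows ordered (kh, kw, c)
  sigmoid_ref(conv2d_ref(stack, kern, w$b))
}

oracle_cbam <- function(x, w) {
  mc <- oracle_channel_attention(x, w$ca)
  xp <- x
  for (c in seq_len(dim(x)[3L])) xp[, , c] <- x[, , c] * mc[c]
  ms <- oracle_spatial_attention(xp, w$sa)
  for (c in seq_len(dim(x)[3L])) xp[, , c] <- xp[, , c] * ms
  xp
}

# half-pixel-centre bilinear upsampling of a single plane
bilinear_ref <- function(m, H, W) {
  sh <- nrow(m); sw <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    py <- (i - 0.5) * sh / H - 0.5
    px <- (j - 0.5) * sw / W - 0.5
    y0 <- max(0, min(sh - 1, floor(py))); y1 <- min(sh - 1, y0 + 1)
    x0 <- max(0, min(sw - 1, floor(px))); x1 <- min(sw - 1, x0 + 1)
    wy <- min(1, max(0, py - y0)); wx <- min(1, max(0, px - x0))
    out[i, j] <- (1 - wy) * (1 - wx) * m[y0 + 1, x0 + 1] +
      wy * (1 - wx) * m[y1 + 1, x0 + 1] +
      (1 - wy) * wx * m[y0 + 1, x1 + 1] +
      wy * wx * m[y1 + 1, x1 + 1]
  }
  out
}

# attention gate: 1x1 projections of skip and (upsampled) gating signal,
# ReLU of the sum, 1x1 projection + sigmoid -> alpha; attended = alpha * skip
oracle_attention_gate <- function(skip, gate, w) {
  H <- dim(skip)[1L]; W <- dim(skip)[2L]
  Cs <- dim(skip)[3L]; Cg <- dim(gate)[3L]
  gup <- array(0, c(H, W, Cg))
  for (c in seq_len(Cg)) gup[, , c] <- bilinear_ref(gate[, , c, drop = TRUE], H, W)
  ci <- ncol(w$Wx)
  alpha <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    q <- numeric(ci)
    for (m in seq_len(ci)) {
      sx <- sum(skip[i, j, ] * w$Wx[, m]) + w$bx[m]
      sg <- sum(gup[i, j, ] * w$Wg[, m]) + w$bg[m]
      q[m] <- max(0, sx + sg)
    }
    alpha[i, j] <- sigmoid_ref(sum(q * w$Wp[, 1]) + w$bp)
  }
  att <- skip
  for (c in seq_len(Cs)) att[, , c] <- skip[, , c] * alpha
  list(alpha = alpha, attended = att)
}

# exhaustive Mann-Whitney AUC: concordant pairs / (pos * neg), ties 0.5
oracle_auc_pairs <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

rand_feature_map <- function(H, W, C, seed) {
  set.seed(seed)
  array(rnorm(H * W * C), c(H, W, C))
}
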