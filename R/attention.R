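# Triple attention: convolutional block attention (channel + spatial, applied
# sequentially channel-first) and the additive attention gate used on skip
# connections.  Internal *_fwd/*_bwd functions operate on batched (H, W, B, C)
# tensors; the exported wrappers take a single (H, W, C) feature map.

# ---- channel attention -----------------------------------------------------

channel_att_fwd <- function(x, p) {
  d <- dim(x)
  hw <- d[1L] * d[2L]; nbc <- d[3L] * d[4L]
  xm <- x
  dim(xm) <- c(hw, nbc)
  s_avg <- matrix(colMeans(xm), d[3L], d[4L])
  amax <- max.col(t(xm), ties.method = "first")
  s_max <- matrix(xm[amax + hw * (seq_len(nbc) - 1L)], d[3L], d[4L])
  h_avg <- s_avg %*% p$W0 + rep(p$b0, each = d[3L])
  h_max <- s_max %*% p$W0 + rep(p$b0, each = d[3L])
  h_avg <- h_avg * (h_avg > 0)
  h_max <- h_max * (h_max > 0)
  pre <- (h_avg + h_max) %*% p$W1 + rep(2 * p$b1, each = d[3L])
  m <- sigmoid(pre)
  out <- x * rep(as.vector(m), each = hw)
  list(out = out, map = m,
       cache = list(x = x, dims = d, s_avg = s_avg, s_max = s_max,
                    h_avg = h_avg, h_max = h_max, m = m, amax = amax))
}

channel_att_bwd <- function(dy, p, cache) {
  d <- cache$dims
  hw <- d[1L] * d[2L]; nbc <- d[3L] * d[4L]
  mfac <- rep(as.vector(cache$m), each = hw)
  dyx <- dy * cache$x
  dim(dyx) <- c(hw, nbc)
  dm <- matrix(colSums(dyx), d[3L], d[4L])
  dpre <- dm * cache$m * (1 - cache$m)
  dsum <- tcrossprod(dpre, p$W1)
  dW1 <- crossprod(cache$h_avg + cache$h_max, dpre)
  db1 <- 2 * colSums(dpre)
  dha <- dsum * (cache$h_avg > 0)
  dhm <- dsum * (cache$h_max > 0)
  dW0 <- crossprod(cache$s_avg, dha) + crossprod(cache$s_max, dhm)
  db0 <- colSums(dha) + colSums(dhm)
  ds_avg <- tcrossprod(dha, p$W0)
  ds_max <- tcrossprod(dhm, p$W0)
  dx <- dy * mfac + rep(as.vector(ds_avg) / hw, each = hw)
  idx <- cache$amax + hw * (seq_len(nbc) - 1L)
  dx[idx] <- dx[idx] + as.vector(ds_max)
  dim(dx) <- d
  list(dx = dx, grads = list(W0 = dW0, b0 = db0, W1 = dW1, b1 = db1))
}

# ---- spatial attention -----------------------------------------------------

channel_pool <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(prod(d[1:3]), d[4L])
  avg <- rowMeans(xm)
  mx <- xm[, 1L]
  arg <- rep(1L, length(mx))
  if (d[4L] > 1L) {
    for (ch in 2:d[4L]) {
      v <- xm[, ch]
      upd <- v > mx
      mx[upd] <- v[upd]
      arg[upd] <- ch
    }
  }
  list(avg = avg, mx = mx, arg = arg)
}

spatial_att_fwd <- function(x, p) {
  d <- dim(x)
  cp <- channel_pool(x)
  s <- array(c(cp$avg, cp$mx), c(d[1L], d[2L], d[3L], 2L))
  cv <- conv2d_fwd(s, p$W, p$b, 7L)
  ms <- sigmoid(cv$out)
  out <- x * as.vector(ms)
  list(out = out, map = ms,
       cache = list(x = x, dims = d, ms = ms, conv = cv$cache, arg = cp$arg))
}

spatial_att_bwd <- function(dy, p, cache) {
  d <- cache$dims
  n <- prod(d[1:3])
  dyx <- dy * cache$x
  dim(dyx) <- c(n, d[4L])
  dms <- rowSums(dyx)
  dim(dms) <- c(d[1L], d[2L], d[3L], 1L)
  dpre <- sigmoid_bwd(dms, cache$ms)
  cb <- conv2d_bwd(dpre, p$W, cache$conv)
  davg <- as.vector(cb$dx[, , , 1L, drop = FALSE])
  dmax <- as.vector(cb$dx[, , , 2L, drop = FALSE])
  dx <- dy * as.vector(cache$ms) + davg / d[4L]
  idx <- seq_len(n) + n * (cache$arg - 1L)
  dx[idx] <- dx[idx] + dmax
  dim(dx) <- d
  list(dx = dx, grads = list(W = cb$dW, b = cb$db))
}

# ---- CBAM: channel-first sequential composition ---------------------------

cbam_fwd <- function(x, p) {
  ca <- channel_att_fwd(x, p$ca)
  sa <- spatial_att_fwd(ca$out, p$sa)
  list(out = sa$out, cache = list(ca = ca$cache, sa = sa$cache))
}

cbam_bwd <- function(dy, p, cache) {
  sb <- spatial_att_bwd(dy, p$sa, cache$sa)
  cbk <- channel_att_bwd(sb$dx, p$ca, cache$ca)
  list(dx = cbk$dx, grads = list(ca = cbk$grads, sa = sb$grads))
}

# ---- attention gate --------------------------------------------------------

attention_gate_fwd <- function(skip, gate, p) {
  d <- dim(skip)
  n <- prod(d[1:3])
  up <- bilinear_resample_fwd(gate, d[1L], d[2L])
  gm <- up$out
  dim(gm) <- c(n, dim(gate)[4L])
  sm <- skip
  dim(sm) <- c(n, d[4L])
  gx <- gm %*% p$Wg + rep(p$bg, each = n)
  xx <- sm %*% p$Wx + rep(p$bx, each = n)
  q <- gx + xx
  q <- q * (q > 0)
  pre <- q %*% p$Wp
  alpha <- sigmoid(pre + as.numeric(p$bp))
  out <- skip * as.vector(alpha)
  amap <- alpha
  dim(amap) <- c(d[1L], d[2L], d[3L], 1L)
  list(out = out, alpha = amap,
       cache = list(dims = d, skip = skip, sm = sm, gm = gm, q = q,
                    alpha = alpha, up = up$cache, gdim = dim(gate)))
}

attention_gate_bwd <- function(dy, p, cache) {
  d <- cache$dims
  n <- prod(d[1:3])
  dys <- dy * cache$skip
  dim(dys) <- c(n, d[4L])
  dalpha <- rowSums(dys)
  dpre <- dalpha * cache$alpha * (1 - cache$alpha)
  dWp <- crossprod(cache$q, dpre)
  dbp <- sum(dpre)
  dq <- tcrossprod(dpre, p$Wp) * (cache$q > 0)
  dWx <- crossprod(cache$sm, dq)
  dbx <- colSums(dq)
  dWg <- crossprod(cache$gm, dq)
  dbg <- colSums(dq)
  dskip <- dy * as.vector(cache$alpha) +
    array(tcrossprod(dq, p$Wx), d)
  dup <- tcrossprod(dq, p$Wg)
  dim(dup) <- c(d[1L], d[2L], d[3L], cache$gdim[4L])
  dgate <- bilinear_resample_bwd(dup, cache$up)
  list(dskip = dskip, dgate = dgate,
       grads = list(Wx = dWx, bx = dbx, Wg = dWg, bg = dbg,
                    Wp = dWp, bp = dbp))
}

# ---- weight constructors ---------------------------------------------------

init_channel_att <- function(channels, r) {
  hidden <- max(1L, as.integer(round(channels / r)))
  w0 <- init_dense(channels, hidden)
  w1 <- init_dense(hidden, channels)
  list(W0 = w0$W, b0 = w0$b, W1 = w1$W, b1 = w1$b)
}

init_spatial_att <- function() init_conv(7L, 2L, 1L)

init_cbam <- function(channels, r) {
  list(ca = init_channel_att(channels, r), sa = init_spatial_att())
}

init_attention_gate <- function(skip_channels, gating_channels, inter_channels) {
  if (inter_channels <= 0) stop("inter_channels must be positive")
  list(Wx = init_dense(skip_channels, inter_channels)$W,
       bx = numeric(inter_channels),
       Wg = init_dense(gating_channels, inter_channels)$W,
       bg = numeric(inter_channels),
       Wp = init_dense(inter_channels, 1L)$W,
       bp = 0)
}

as_batch1 <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) d <- c(d, 1L)
  array(x, c(d[1L], d[2L], 1L, d[3L]))
}

#' Channel attention map
#'
#' Squeezes a feature map to per-channel descriptors by global average and
#' max pooling, passes both through a shared one-hidden-layer perceptron
#' (hidden width `C / r`, rectified), sums the two outputs and applies a
#' sigmoid.  The result weights each channel by its estimated relevance.
#'
#' @param x numeric array `H x W x C`, a single feature map.
#' @param weights weight list from [channel_attention_weights()]; channel
#'   count must match `x`.
#' @param r reduction ratio of the shared perceptron (used only when
#'   `weights` is missing).
#' @return numeric vector of length `C` with entries strictly in (0, 1).
#' @export
channel_attention <- function(x, weights = NULL, r = 16) {
  if (r <= 0) stop("reduction ratio must be positive")
  xb <- as_batch1(x)
  C <- dim(xb)[4L]
  if (is.null(weights)) weights <- channel_attention_weights(C, r)
  as.vector(channel_att_fwd(xb, weights)$map)
}

#' @rdname channel_attention
#' @param channels number of input channels.
#' @export
channel_attention_weights <- function(channels, r = 16) {
  if (r <= 0) stop("reduction ratio must be positive")
  init_channel_att(channels, r)
}

#' Spatial attention map
#'
#' Pools a feature map across channels (mean and max), stacks the two maps,
#' convolves them with a single 7x7 kernel (same padding) and applies a
#' sigmoid, giving one attention weight per spatial location.
#'
#' @param x numeric array `H x W x C`.
#' @param weights weight list from [spatial_attention_weights()].
#' @return numeric matrix `H x W` with entries strictly in (0, 1).
#' @export
spatial_attention <- function(x, weights = NULL) {
  xb <- as_batch1(x)
  if (is.null(weights)) weights <- spatial_attention_weights()
  m <- spatial_att_fwd(xb, weights)$map
  matrix(m, dim(xb)[1L], dim(xb)[2L])
}

#' @rdname spatial_attention
#' @export
spatial_attention_weights <- function() init_spatial_att()

#' Convolutional block attention (CBAM)
#'
#' Applies channel attention then spatial attention, each multiplicatively,
#' in the sequential channel-first arrangement.  Both maps lie in (0, 1), so
#' the refined features never exceed the input in absolute value.
#'
#' @param x numeric array `H x W x C`.
#' @param weights weight list from [cbam_weights()].
#' @return refined feature map, same shape as `x`.
#' @export
cbam <- function(x, weights = NULL) {
  xb <- as_batch1(x)
  C <- dim(xb)[4L]
  if (is.null(weights)) weights <- cbam_weights(C)
  out <- cbam_fwd(xb, weights)$out
  array(out, c(dim(xb)[1L], dim(xb)[2L], C))
}

#' @rdname cbam
#' @param channels number of input channels.
#' @param r reduction ratio of the channel-attention perceptron.
#' @export
cbam_weights <- function(channels, r = 16) init_cbam(channels, r)

#' Attention gate for skip connections
#'
#' Projects the skip features and a coarser gating signal to a common
#' intermediate width with 1x1 convolutions, resamples the gating signal
#' bilinearly onto the skip grid, adds the projections, rectifies, and maps
#' the result through a final 1x1 convolution and sigmoid to a spatial
#' coefficient map `alpha` in (0, 1) that rescales the skip features.
#'
#' @param skip numeric array `H x W x C_s`, encoder features.
#' @param gating numeric array `h x w x C_g` with `h <= H`, `w <= W`, the
#'   coarser decoder signal.
#' @param weights weight list from [attention_gate_weights()].
#' @return list with `alpha` (`H x W` matrix in (0, 1)) and `attended`
#'   (`H x W x C_s`, equal to `skip` scaled by `alpha`).
#' @export
attention_gate <- function(skip, gating, weights = NULL) {
  sb <- as_batch1(skip)
  gb <- as_batch1(gating)
  if (any(dim(gb)[1:2] > dim(sb)[1:2]))
    stop("gating signal must not be finer than the skip features")
  if (is.null(weights))
    weights <- attention_gate_weights(dim(sb)[4L], dim(gb)[4L],
                                      max(1L, dim(sb)[4L] %/% 2L))
  fw <- attention_gate_fwd(sb, gb, weights)
  list(alpha = matrix(fw$alpha, dim(sb)[1L], dim(sb)[2L]),
       attended = array(fw$out, c(dim(sb)[1L], dim(sb)[2L], dim(sb)[4L])))
}

#' @rdname attention_gate
#' @param skip_channels,gating_channels,inter_channels channel counts of the
#'   skip input, gating input, and shared intermediate projection.
#' @export
attention_gate_weights <- function(skip_channels, gating_channels,
                                   inter_channels) {
  init_attention_gate(skip_channels, gating_channels, inter_channels)
}
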