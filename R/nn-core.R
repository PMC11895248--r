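# Low-level differentiable tensor operations.
#
# Feature maps are dense R arrays with dim (H, W, B, C): because R arrays are
# column-major, collapsing the first three dims gives a (H*W*B) x C matrix
# without copying, so convolutions and 1x1 projections reduce to BLAS gemm
# calls (see src/kernels.cpp for the k x k case).  Each op comes as a *_fwd
# function returning list(out, cache) and a *_bwd taking the upstream
# gradient plus the cache, mirroring the forward graph exactly.

.cache_env <- new.env(parent = emptyenv())

#' @useDynLib masegnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

tensor_dims <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  list(H = d[1L], W = d[2L], B = d[3L], C = d[4L])
}

# ---- convolution (same padding) -------------------------------------------

conv2d_fwd <- function(x, W, b, k) {
  d <- dim(x)
  if (is.null(b)) b <- numeric(ncol(W))
  y <- conv2d_same_fwd(x, d[1L], d[2L], d[3L], d[4L], W, b, k)
  list(out = y, cache = list(dims = d, k = k, x = x))
}

conv2d_bwd <- function(dy, W, cache) {
  d <- cache$dims
  r <- conv2d_same_bwd(dy, cache$x, d[1L], d[2L], d[3L], d[4L], W, cache$k)
  list(dx = r$dx, dW = r$dW, db = r$db)
}

# ---- 2x2 transposed convolution, stride 2 ---------------------------------
# Stride equals kernel size, so output taps never overlap: each of the four
# kernel offsets is an independent 1x1 convolution written to an interleaved
# sub-grid of the doubled output.

tconv2x2_fwd <- function(x, W, b) {
  d <- dim(x)
  cin <- d[4L]; cout <- dim(W)[4L]
  xm <- x
  dim(xm) <- c(prod(d[1:3]), cin)
  out <- array(0, c(2L * d[1L], 2L * d[2L], d[3L], cout))
  for (dy in 0:1) for (dx in 0:1) {
    y <- xm %*% matrix(W[dy + 1L, dx + 1L, , ], cin, cout)
    dim(y) <- c(d[1L], d[2L], d[3L], cout)
    out[seq(1L + dy, 2L * d[1L], 2L), seq(1L + dx, 2L * d[2L], 2L), , ] <- y
  }
  out <- out + rep(b, each = prod(dim(out)[1:3]))
  list(out = out, cache = list(xm = xm, dims = d, cout = cout))
}

tconv2x2_bwd <- function(dy, W, cache) {
  d <- cache$dims
  cin <- d[4L]; cout <- cache$cout
  dW <- array(0, dim(W))
  dxm <- matrix(0, nrow(cache$xm), cin)
  for (py in 0:1) for (px in 0:1) {
    g <- dy[seq(1L + py, 2L * d[1L], 2L), seq(1L + px, 2L * d[2L], 2L), , , drop = FALSE]
    dim(g) <- c(prod(d[1:3]), cout)
    dW[py + 1L, px + 1L, , ] <- crossprod(cache$xm, g)
    dxm <- dxm + tcrossprod(g, matrix(W[py + 1L, px + 1L, , ], cin, cout))
  }
  db <- colSums(matrix(dy, ncol = cout))
  dim(dxm) <- d
  list(dx = dxm, dW = dW, db = db)
}

# ---- 2x2 max pooling, stride 2 --------------------------------------------

maxpool2x2_fwd <- function(x) {
  d <- dim(x)
  ri <- seq(1L, d[1L], 2L); ci <- seq(1L, d[2L], 2L)
  a00 <- x[ri, ci, , , drop = FALSE]
  a10 <- x[ri + 1L, ci, , , drop = FALSE]
  a01 <- x[ri, ci + 1L, , , drop = FALSE]
  a11 <- x[ri + 1L, ci + 1L, , , drop = FALSE]
  out <- pmax(a00, a10, a01, a11)
  # first-max tie break so each output pixel routes gradient to one input
  m00 <- a00 == out
  m10 <- (a10 == out) & !m00
  m01 <- (a01 == out) & !(m00 | m10)
  m11 <- !(m00 | m10 | m01)
  list(out = out, cache = list(dims = d, m = list(m00, m10, m01, m11)))
}

maxpool2x2_bwd <- function(dy, cache) {
  d <- cache$dims
  ri <- seq(1L, d[1L], 2L); ci <- seq(1L, d[2L], 2L)
  dx <- array(0, d)
  dx[ri, ci, , ] <- dy * cache$m[[1L]]
  dx[ri + 1L, ci, , ] <- dy * cache$m[[2L]]
  dx[ri, ci + 1L, , ] <- dy * cache$m[[3L]]
  dx[ri + 1L, ci + 1L, , ] <- dy * cache$m[[4L]]
  dx
}

# ---- activations -----------------------------------------------------------

relu_fwd <- function(x) {
  out <- x * (x > 0)
  list(out = out, cache = out)
}

relu_bwd <- function(dy, cache) dy * (cache > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# d sigmoid = s * (1 - s), applied from the cached output
sigmoid_bwd <- function(dy, s) dy * s * (1 - s)

# ---- bilinear resampling ---------------------------------------------------
# Half-pixel-centre convention: destination pixel i samples the source at
# (i + 0.5) * src/dst - 0.5.  The whole map is a sparse (dst_h*dst_w) x
# (src_h*src_w) matrix, so the adjoint (needed for backprop through the
# attention-gate upsampling) is just the transpose.  Matrices are cached per
# geometry.

bilinear_matrix <- function(src_h, src_w, dst_h, dst_w) {
  key <- paste("bl", src_h, src_w, dst_h, dst_w, sep = "_")
  hit <- .cache_env[[key]]
  if (!is.null(hit)) return(hit)
  axis_weights <- function(src, dst) {
    pos <- (seq_len(dst) - 0.5) * src / dst - 0.5
    i0 <- pmax(0L, pmin(src - 1L, floor(pos)))
    i1 <- pmin(src - 1L, i0 + 1L)
    w1 <- pmin(1, pmax(0, pos - i0))
    list(i0 = as.integer(i0), i1 = as.integer(i1), w0 = 1 - w1, w1 = w1)
  }
  ay <- axis_weights(src_h, dst_h)
  ax <- axis_weights(src_w, dst_w)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  ridx <- seq_len(dst_h * dst_w)
  for (cy in 1:2) for (cx in 1:2) {
    yi <- if (cy == 1) ay$i0 else ay$i1
    yw <- if (cy == 1) ay$w0 else ay$w1
    xi <- if (cx == 1) ax$i0 else ax$i1
    xw <- if (cx == 1) ax$w0 else ax$w1
    src_idx <- outer(yi, xi, function(a, b) a + src_h * b) + 1L
    wts <- outer(yw, xw)
    rows <- c(rows, ridx); cols <- c(cols, as.integer(src_idx))
    vals <- c(vals, as.numeric(wts))
  }
  S <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(dst_h * dst_w, src_h * src_w))
  .cache_env[[key]] <- S
  S
}

# x: (H, W, B, C) -> (dst_h, dst_w, B, C)
bilinear_resample_fwd <- function(x, dst_h, dst_w) {
  d <- dim(x)
  S <- bilinear_matrix(d[1L], d[2L], dst_h, dst_w)
  dim(x) <- c(d[1L] * d[2L], d[3L] * d[4L])
  y <- as.matrix(S %*% x)
  dim(y) <- c(dst_h, dst_w, d[3L], d[4L])
  list(out = y, cache = list(S = S, dims = d))
}

bilinear_resample_bwd <- function(dy, cache) {
  d <- cache$dims
  dim(dy) <- c(nrow(cache$S), d[3L] * d[4L])
  dx <- as.matrix(Matrix::crossprod(cache$S, dy))
  dim(dx) <- d
  dx
}

# ---- parameter initialisation ---------------------------------------------

he_uniform <- function(fan_in, dims) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

init_conv <- function(k, cin, cout) {
  list(W = matrix(he_uniform(k * k * cin, c(k * k * cin, cout)),
                  k * k * cin, cout),
       b = numeric(cout))
}

init_tconv <- function(cin, cout) {
  list(W = he_uniform(4 * cin, c(2L, 2L, cin, cout)), b = numeric(cout))
}

init_dense <- function(cin, cout) {
  list(W = matrix(he_uniform(cin, c(cin, cout)), cin, cout),
       b = numeric(cout))
}

# ---- nested parameter-list utilities --------------------------------------

# apply f to every leaf array of a nested parameter list, in parallel over
# several structurally identical lists (used by the Adam update)
param_map <- function(f, ...) {
  lists <- list(...)
  x <- lists[[1L]]
  if (is.list(x)) {
    keys <- if (is.null(names(x))) seq_along(x) else names(x)
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(keys))
      out[[i]] <- do.call(param_map, c(list(f), lapply(lists, `[[`, keys[[i]])))
    out
  } else {
    do.call(f, lists)
  }
}

param_count <- function(params) {
  if (is.list(params)) sum(vapply(params, param_count, numeric(1))) else length(params)
}

# flat named vector of leaf paths -> used by tests poking single weights
param_leaves <- function(params, prefix = "") {
  if (!is.list(params)) return(stats::setNames(list(params), prefix))
  keys <- names(params)
  if (is.null(keys)) keys <- as.character(seq_along(params))
  out <- list()
  for (i in seq_along(params))
    out <- c(out, param_leaves(params[[i]],
                               if (nzchar(prefix)) paste0(prefix, ".", keys[i]) else keys[i]))
  out
}
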