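# CBAM-AG-UNet: a U-shaped encoder-decoder for tiny-lesion segmentation.
# Each encoder step is double 3x3 conv + ReLU, refined by CBAM, then 2x2
# max-pooled; filter counts double at every downsampling stage up to the
# bottleneck.  Each decoder step gates the skip features with an attention
# gate driven by the coarser decoder signal, upsamples by a 2x2 transposed
# convolution, concatenates, normalises with double 3x3 conv + ReLU and
# refines the result with CBAM (the three-fold attention block).  The head
# is a 1x1 convolution + sigmoid, giving per-pixel lesion probabilities.

#' Model configuration
#'
#' @param in_channels input channels (1 for preprocessed grayscale patches,
#'   3 for raw RGB).
#' @param base_filters filters of the first encoder stage; doubled at every
#'   downsampling step.
#' @param depth number of downsampling stages.
#' @param bottleneck_filters filters at the deepest stage; must equal
#'   `base_filters * 2^depth` (512 for the default ladder, 256 for the
#'   narrow ablation with `base_filters = 16`).
#' @param reduction_ratio reduction ratio of the channel-attention
#'   perceptron.
#' @param use_cbam include CBAM blocks in encoder, decoder and bottleneck.
#' @param use_ag include attention gates on the skip connections.
#' @param cbam_bottleneck include CBAM in the bottleneck (only when
#'   `use_cbam` is `TRUE`).
#' @return a `masegnet_config` list.
#' @export
model_config <- function(in_channels = 1L, base_filters = 32L, depth = 4L,
                         bottleneck_filters = base_filters * 2^depth,
                         reduction_ratio = 16L, use_cbam = TRUE,
                         use_ag = TRUE, cbam_bottleneck = TRUE) {
  if (depth < 1) stop("depth must be at least 1")
  if (reduction_ratio <= 0) stop("reduction_ratio must be positive")
  if (bottleneck_filters != base_filters * 2^depth)
    stop("bottleneck_filters must equal base_filters * 2^depth (got ",
         bottleneck_filters, ", expected ", base_filters * 2^depth, ")")
  structure(list(in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters),
                 depth = as.integer(depth),
                 bottleneck_filters = as.integer(bottleneck_filters),
                 reduction_ratio = as.integer(reduction_ratio),
                 use_cbam = isTRUE(use_cbam),
                 use_ag = isTRUE(use_ag),
                 cbam_bottleneck = isTRUE(cbam_bottleneck)),
            class = "masegnet_config")
}

stage_filters <- function(config) config$base_filters * 2^(seq_len(config$depth) - 1L)

init_double_conv <- function(cin, f) {
  list(conv1 = init_conv(3L, cin, f), conv2 = init_conv(3L, f, f))
}

#' Build a CBAM-AG-UNet model
#'
#' Initialises all weights (He-uniform, biases zero) under the given seed.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialisation.
#' @param head_bias initial bias of the output 1x1 convolution.  Setting it
#'   to the log-odds of the foreground pixel fraction (e.g. `qlogis(0.005)`)
#'   starts training at the class prior, which markedly shortens the early
#'   phase on heavily imbalanced masks.
#' @return a `masegnet_model` list with elements `config` and `params`.
#' @export
build_model <- function(config = model_config(), seed = 1L, head_bias = 0) {
  stopifnot(inherits(config, "masegnet_config"))
  set.seed(seed)
  f <- stage_filters(config)
  r <- config$reduction_ratio
  params <- list()
  cin <- config$in_channels
  params$enc <- vector("list", config$depth)
  for (i in seq_len(config$depth)) {
    blk <- init_double_conv(cin, f[i])
    if (config$use_cbam) blk$cbam <- init_cbam(f[i], r)
    params$enc[[i]] <- blk
    cin <- f[i]
  }
  bn <- config$bottleneck_filters
  params$bottleneck <- init_double_conv(f[config$depth], bn)
  if (config$use_cbam && config$cbam_bottleneck)
    params$bottleneck$cbam <- init_cbam(bn, r)
  params$dec <- vector("list", config$depth)
  up_in <- bn
  for (i in rev(seq_len(config$depth))) {
    blk <- list(up = init_tconv(up_in, f[i]))
    if (config$use_ag)
      blk$ag <- init_attention_gate(f[i], up_in, max(1L, f[i] %/% 2L))
    blk <- c(blk, init_double_conv(2L * f[i], f[i]))
    if (config$use_cbam) blk$cbam <- init_cbam(f[i], r)
    params$dec[[i]] <- blk
    up_in <- f[i]
  }
  params$head <- init_dense(f[1L], 1L)
  params$head$b <- head_bias
  structure(list(config = config, params = params), class = "masegnet_model")
}

double_conv_fwd <- function(x, p) {
  c1 <- conv2d_fwd(x, p$conv1$W, p$conv1$b, 3L)
  r1 <- relu_fwd(c1$out)
  c2 <- conv2d_fwd(r1$out, p$conv2$W, p$conv2$b, 3L)
  r2 <- relu_fwd(c2$out)
  list(out = r2$out, cache = list(c1 = c1$cache, r1 = r1$cache,
                                  c2 = c2$cache, r2 = r2$cache))
}

double_conv_bwd <- function(dy, p, cache) {
  dy <- relu_bwd(dy, cache$r2)
  b2 <- conv2d_bwd(dy, p$conv2$W, cache$c2)
  dx <- relu_bwd(b2$dx, cache$r1)
  b1 <- conv2d_bwd(dx, p$conv1$W, cache$c1)
  list(dx = b1$dx, grads = list(conv1 = list(W = b1$dW, b = b1$db),
                                conv2 = list(W = b2$dW, b = b2$db)))
}

#' Forward pass
#'
#' @param model a `masegnet_model`.
#' @param x input array: `H x W x C` (single image) or `H x W x B x C`
#'   (batch); `H` and `W` must be divisible by `2^depth`.
#' @param tape keep the caches needed for backpropagation.
#' @return list with `out` (probabilities in (0, 1), `H x W x B x 1`) and,
#'   when `tape = TRUE`, the cache structure consumed by the internal
#'   backward pass.
#' @export
model_forward <- function(model, x, tape = FALSE) {
  cfg <- model$config
  p <- model$params
  if (length(dim(x)) == 3L) x <- as_batch1(x)
  d <- dim(x)
  if (d[4L] != cfg$in_channels)
    stop("input has ", d[4L], " channels, model expects ", cfg$in_channels)
  if (any(d[1:2] %% 2^cfg$depth != 0))
    stop("spatial dims (", d[1L], "x", d[2L], ") must be divisible by 2^depth = ",
         2^cfg$depth)
  tp <- list(enc = vector("list", cfg$depth),
             dec = vector("list", cfg$depth))
  skips <- vector("list", cfg$depth)
  cur <- x
  for (i in seq_len(cfg$depth)) {
    dc <- double_conv_fwd(cur, p$enc[[i]])
    feat <- dc$out
    cbc <- NULL
    if (cfg$use_cbam) {
      cb <- cbam_fwd(feat, p$enc[[i]]$cbam)
      feat <- cb$out
      cbc <- cb$cache
    }
    mp <- maxpool2x2_fwd(feat)
    skips[[i]] <- feat
    tp$enc[[i]] <- list(dc = dc$cache, cbam = cbc, pool = mp$cache)
    cur <- mp$out
  }
  dc <- double_conv_fwd(cur, p$bottleneck)
  cur <- dc$out
  bnc <- list(dc = dc$cache, cbam = NULL)
  if (cfg$use_cbam && cfg$cbam_bottleneck) {
    cb <- cbam_fwd(cur, p$bottleneck$cbam)
    cur <- cb$out
    bnc$cbam <- cb$cache
  }
  tp$bottleneck <- bnc
  for (i in rev(seq_len(cfg$depth))) {
    blk <- p$dec[[i]]
    skip <- skips[[i]]
    agc <- NULL
    att <- skip
    if (cfg$use_ag) {
      ag <- attention_gate_fwd(skip, cur, blk$ag)
      att <- ag$out
      agc <- ag$cache
    }
    up <- tconv2x2_fwd(cur, blk$up$W, blk$up$b)
    ds <- dim(skip)
    du <- dim(up$out)
    if (any(du[1:2] != ds[1:2]))
      stop("decoder/skip spatial mismatch: upsampled ", du[1L], "x", du[2L],
           " vs skip ", ds[1L], "x", ds[2L])
    fi <- ds[4L]
    z <- array(0, c(ds[1L], ds[2L], ds[3L], 2L * fi))
    z[, , , seq_len(fi)] <- up$out
    z[, , , fi + seq_len(fi)] <- att
    dc <- double_conv_fwd(z, blk)
    cur <- dc$out
    cbc <- NULL
    if (cfg$use_cbam) {
      cb <- cbam_fwd(cur, blk$cbam)
      cur <- cb$out
      cbc <- cb$cache
    }
    tp$dec[[i]] <- list(ag = agc, up = up$cache, dc = dc$cache,
                        cbam = cbc, fi = fi)
  }
  n <- prod(dim(cur)[1:3])
  hm <- cur
  dim(hm) <- c(n, dim(cur)[4L])
  pre <- hm %*% p$head$W + p$head$b
  prob <- sigmoid(pre)
  dim(prob) <- c(d[1L], d[2L], d[3L], 1L)
  tp$head <- list(hm = hm, din = dim(cur))
  list(out = prob, tape = if (tape) tp else NULL)
}

# dz: gradient w.r.t. the pre-sigmoid head activation (H, W, B, 1)
model_backward <- function(model, tp, dz) {
  cfg <- model$config
  p <- model$params
  g <- list(enc = vector("list", cfg$depth),
            dec = vector("list", cfg$depth))
  hm <- tp$head$hm
  dzm <- matrix(dz, nrow(hm), 1L)
  g$head <- list(W = crossprod(hm, dzm), b = sum(dzm))
  dcur <- tcrossprod(dzm, p$head$W)
  dim(dcur) <- tp$head$din
  dskips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    blk <- p$dec[[i]]
    tpi <- tp$dec[[i]]
    gi <- list()
    if (cfg$use_cbam) {
      cb <- cbam_bwd(dcur, blk$cbam, tpi$cbam)
      dcur <- cb$dx
      gi$cbam <- cb$grads
    }
    dc <- double_conv_bwd(dcur, blk, tpi$dc)
    gi$conv1 <- dc$grads$conv1
    gi$conv2 <- dc$grads$conv2
    fi <- tpi$fi
    dup <- dc$dx[, , , seq_len(fi), drop = FALSE]
    datt <- dc$dx[, , , fi + seq_len(fi), drop = FALSE]
    tb <- tconv2x2_bwd(dup, blk$up$W, tpi$up)
    gi$up <- list(W = tb$dW, b = tb$db)
    dnext <- tb$dx
    if (cfg$use_ag) {
      ab <- attention_gate_bwd(datt, blk$ag, tpi$ag)
      gi$ag <- ab$grads
      dskips[[i]] <- ab$dskip
      dnext <- dnext + ab$dgate
    } else {
      dskips[[i]] <- datt
    }
    # reorder grads to the params layout (up, [ag], conv1, conv2, [cbam])
    ord <- c("up", if (cfg$use_ag) "ag", "conv1", "conv2",
             if (cfg$use_cbam) "cbam")
    g$dec[[i]] <- gi[ord]
    dcur <- dnext
  }
  gb <- list()
  if (cfg$use_cbam && cfg$cbam_bottleneck) {
    cb <- cbam_bwd(dcur, p$bottleneck$cbam, tp$bottleneck$cbam)
    dcur <- cb$dx
    gb$cbam <- cb$grads
  }
  dc <- double_conv_bwd(dcur, p$bottleneck, tp$bottleneck$dc)
  g$bottleneck <- c(dc$grads, gb)
  dcur <- dc$dx
  for (i in rev(seq_len(cfg$depth))) {
    tpi <- tp$enc[[i]]
    dfeat <- maxpool2x2_bwd(dcur, tpi$pool) + dskips[[i]]
    gi <- list()
    if (cfg$use_cbam) {
      cb <- cbam_bwd(dfeat, p$enc[[i]]$cbam, tpi$cbam)
      dfeat <- cb$dx
      gi$cbam <- cb$grads
    }
    dc <- double_conv_bwd(dfeat, p$enc[[i]], tpi$dc)
    g$enc[[i]] <- c(dc$grads, gi)
    dcur <- dc$dx
  }
  g[names(p)]
}

#' Number of trainable parameters
#' @param model a `masegnet_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) param_count(model$params)

#' @export
print.masegnet_model <- function(x, ...) {
  cfg <- x$config
  f <- stage_filters(cfg)
  cat("CBAM-AG-UNet (", if (cfg$use_cbam) "CBAM" else "no CBAM", ", ",
      if (cfg$use_ag) "AG" else "no AG", ")\n", sep = "")
  cat("  input channels:", cfg$in_channels, "\n")
  cat("  encoder filters:", paste(f, collapse = " -> "),
      "| bottleneck:", cfg$bottleneck_filters, "\n")
  cat("  parameters:", format(n_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' Encoder block
#'
#' Double 3x3 convolution + ReLU, optional CBAM refinement, and a 2x2
#' max-pool.  The pre-pool tensor feeds the skip connection.
#'
#' @param x input `H x W x C` array.
#' @param filters output channel count.
#' @param weights weight list from [encoder_block_weights()].
#' @param use_cbam apply CBAM after the convolutions.
#' @return list with `features` (`H x W x filters`) and `pooled`
#'   (`H/2 x W/2 x filters`).
#' @export
encoder_block <- function(x, filters, weights, use_cbam = TRUE) {
  xb <- as_batch1(x)
  dc <- double_conv_fwd(xb, weights)
  feat <- dc$out
  if (use_cbam) feat <- cbam_fwd(feat, weights$cbam)$out
  mp <- maxpool2x2_fwd(feat)
  d <- dim(feat)
  list(features = array(feat, c(d[1L], d[2L], d[4L])),
       pooled = array(mp$out, c(d[1L] / 2L, d[2L] / 2L, d[4L])))
}

#' @rdname encoder_block
#' @param in_channels input channel count.
#' @param r channel-attention reduction ratio.
#' @export
encoder_block_weights <- function(in_channels, filters, r = 16,
                                  use_cbam = TRUE) {
  w <- init_double_conv(in_channels, filters)
  if (use_cbam) w$cbam <- init_cbam(filters, r)
  w
}

#' Three-fold attention decoder block
#'
#' Gates the skip features with an attention gate driven by the coarser
#' decoder signal, upsamples the decoder signal with a 2x2 transposed
#' convolution, concatenates, normalises with double 3x3 convolution + ReLU
#' and refines with CBAM (channel then spatial attention).
#'
#' @param decoder_in `h x w x C_d` decoder features (half the skip
#'   resolution).
#' @param skip `2h x 2w x C_s` encoder features from the skip connection.
#' @param filters output channel count (must equal `C_s`).
#' @param weights weight list from [decoder_block_weights()].
#' @param use_ag,use_cbam ablation toggles.
#' @return `2h x 2w x filters` array.
#' @export
threefold_decoder_block <- function(decoder_in, skip, filters, weights,
                                    use_ag = TRUE, use_cbam = TRUE) {
  db <- as_batch1(decoder_in)
  sb <- as_batch1(skip)
  if (any(dim(sb)[1:2] != 2L * dim(db)[1:2]))
    stop("decoder input must be half the skip resolution: got ",
         paste(dim(db)[1:2], collapse = "x"), " vs skip ",
         paste(dim(sb)[1:2], collapse = "x"))
  att <- if (use_ag) attention_gate_fwd(sb, db, weights$ag)$out else sb
  up <- tconv2x2_fwd(db, weights$up$W, weights$up$b)$out
  d <- dim(sb)
  z <- array(0, c(d[1L], d[2L], 1L, 2L * filters))
  z[, , , seq_len(filters)] <- up
  z[, , , filters + seq_len(filters)] <- att
  out <- double_conv_fwd(z, weights)$out
  if (use_cbam) out <- cbam_fwd(out, weights$cbam)$out
  array(out, c(d[1L], d[2L], filters))
}

#' @rdname threefold_decoder_block
#' @param decoder_channels,skip_channels channel counts of the two inputs.
#' @export
decoder_block_weights <- function(decoder_channels, skip_channels, filters,
                                  r = 16, use_ag = TRUE, use_cbam = TRUE) {
  stopifnot(filters == skip_channels)
  w <- list(up = init_tconv(decoder_channels, filters))
  if (use_ag)
    w$ag <- init_attention_gate(skip_channels, decoder_channels,
                                max(1L, skip_channels %/% 2L))
  w <- c(w, init_double_conv(2L * filters, filters))
  if (use_cbam) w$cbam <- init_cbam(filters, r)
  w
}
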