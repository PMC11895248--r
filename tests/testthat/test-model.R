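test_that("channel attention matches the loop-based oracle", {
  for (seed in 1:3) {
    x <- rand_feature_map(5, 5, 4, seed)
    set.seed(seed + 100)
    w <- channel_attention_weights(4, r = 2)
    got <- channel_attention(x, w)
    ref <- oracle_channel_attention(x, w)
    expect_equal(got, ref, tolerance = 1e-5)
    expect_true(all(got > 0 & got < 1))
  }
  expect_error(channel_attention(rand_feature_map(3, 3, 2, 1), r = 0),
               "positive")
})

test_that("zeroed channel-attention weights give a uniform 0.5 map", {
  w <- channel_attention_weights(4, r = 2)
  w <- lapply(w, function(p) p * 0)
  got <- channel_attention(rand_feature_map(6, 6, 4, 2), w)
  expect_equal(got, rep(0.5, 4))
})

test_that("spatially constant channels make avg and max pooling agree", {
  x <- array(rep(c(1.5, -0.7, 0.2), each = 16), c(4, 4, 3))
  set.seed(11)
  w <- channel_attention_weights(3, r = 1)
  got <- channel_attention(x, w)
  v <- c(1.5, -0.7, 0.2)
  mlp <- function(s) {
    h <- pmax(as.vector(s %*% w$W0) + w$b0, 0)
    as.vector(h %*% w$W1) + w$b1
  }
  expect_equal(got, 1 / (1 + exp(-2 * mlp(v))), tolerance = 1e-10)
})

test_that("spatial attention matches a direct 7x7 convolution oracle", {
  for (seed in 4:6) {
    x <- rand_feature_map(9, 9, 3, seed)
    set.seed(seed + 200)
    w <- spatial_attention_weights()
    got <- spatial_attention(x, w)
    ref <- oracle_spatial_attention(x, w)
    expect_equal(got, ref, tolerance = 1e-5)
    expect_true(all(got > 0 & got < 1))
  }
  # zero kernel -> sigmoid(0) = 0.5 everywhere
  w0 <- list(W = matrix(0, 98, 1), b = 0)
  expect_true(all(spatial_attention(rand_feature_map(5, 5, 2, 1), w0) == 0.5))
  # single-channel input: mean map equals max map equals the input
  x1 <- rand_feature_map(6, 6, 1, 9)
  set.seed(300)
  w <- spatial_attention_weights()
  stack <- array(c(x1[, , 1], x1[, , 1]), c(6, 6, 2))
  ref <- 1 / (1 + exp(-(conv2d_ref(stack, array(w$W, c(7, 7, 2)), w$b))))
  expect_equal(spatial_attention(x1, w), ref, tolerance = 1e-10)
})

test_that("CBAM equals the sequential composition of its two oracles", {
  for (seed in 7:9) {
    x <- rand_feature_map(8, 8, 4, seed)
    set.seed(seed + 400)
    w <- cbam_weights(4, r = 2)
    got <- cbam(x, w)
    ref <- oracle_cbam(x, w)
    expect_equal(got, ref, tolerance = 1e-5)
    # contraction: both maps lie in (0,1)
    expect_true(all(abs(got) <= abs(x) + 1e-12))
  }
})

test_that("the attention gate matches a hand-coded evaluation", {
  for (seed in 10:12) {
    skip <- rand_feature_map(4, 4, 2, seed)
    gate <- rand_feature_map(2, 2, 3, seed + 1)
    set.seed(seed + 500)
    w <- attention_gate_weights(2, 3, 2)
    got <- attention_gate(skip, gate, w)
    ref <- oracle_attention_gate(skip, gate, w)
    expect_equal(got$alpha, ref$alpha, tolerance = 1e-5)
    expect_equal(got$attended, ref$attended, tolerance = 1e-5)
    expect_true(all(got$alpha > 0 & got$alpha < 1))
    expect_true(all(abs(got$attended) <= abs(skip) + 1e-12))
  }
  expect_error(attention_gate_weights(2, 3, 0), "positive")
})

test_that("a zeroed final gate projection halves the skip features", {
  skip <- rand_feature_map(4, 4, 3, 20)
  gate <- rand_feature_map(2, 2, 2, 21)
  set.seed(600)
  w <- attention_gate_weights(3, 2, 2)
  w$Wp <- w$Wp * 0; w$bp <- 0
  got <- attention_gate(skip, gate, w)
  expect_true(all(got$alpha == 0.5))
  expect_equal(got$attended, skip / 2, tolerance = 1e-12)
})

test_that("encoder block honours shapes, toggles, and pooling semantics", {
  x <- rand_feature_map(16, 16, 3, 30)
  set.seed(700)
  w <- encoder_block_weights(3, 8, r = 2)
  out <- encoder_block(x, 8, w, use_cbam = TRUE)
  expect_equal(dim(out$features), c(16L, 16L, 8L))
  expect_equal(dim(out$pooled), c(8L, 8L, 8L))
  # pooled equals an explicit 2x2 window max of the features
  ref <- array(0, c(8, 8, 8))
  for (c in 1:8) for (i in 1:8) for (j in 1:8)
    ref[i, j, c] <- max(out$features[(2 * i - 1):(2 * i),
                                     (2 * j - 1):(2 * j), c])
  expect_equal(out$pooled, ref, tolerance = 1e-12)
  # with CBAM off the features are the plain double-conv output
  plain <- encoder_block(x, 8, w, use_cbam = FALSE)
  expect_false(isTRUE(all.equal(plain$features, out$features)))
})

test_that("decoder block shapes and ablation identities hold", {
  dec <- rand_feature_map(8, 8, 16, 40)
  skip <- rand_feature_map(16, 16, 8, 41)
  set.seed(800)
  w <- decoder_block_weights(16, 8, 8, r = 2)
  out <- threefold_decoder_block(dec, skip, 8, w)
  expect_equal(dim(out), c(16L, 16L, 8L))
  out2 <- threefold_decoder_block(dec, skip, 8, w, use_ag = FALSE,
                                  use_cbam = FALSE)
  expect_equal(dim(out2), c(16L, 16L, 8L))
  expect_error(threefold_decoder_block(rand_feature_map(5, 5, 16, 1), skip,
                                       8, w), "half the skip")
})

test_that("model construction follows the filter ladder and validates config", {
  cfg <- model_config()
  expect_equal(cfg$bottleneck_filters, 512L)
  expect_error(model_config(base_filters = 32, depth = 4,
                            bottleneck_filters = 256), "bottleneck_filters")
  # narrow ablation ladder: base 16 -> bottleneck 256
  m256 <- build_model(model_config(base_filters = 16L), seed = 2)
  expect_equal(m256$config$bottleneck_filters, 256L)
  x <- array(runif(64 * 64), c(64, 64, 1))
  out <- model_forward(m256, x)$out
  expect_equal(dim(out), c(64L, 64L, 1L, 1L))
  expect_true(all(out > 0 & out < 1))
})

test_that("forward output matches input resolution and the sigmoid range", {
  m <- build_model(model_config(base_filters = 4L, depth = 2L,
                                reduction_ratio = 2L), seed = 3)
  for (p in c(16L, 32L)) {
    out <- model_forward(m, array(runif(p * p), c(p, p, 1)))$out
    expect_equal(dim(out)[1:2], c(p, p))
    expect_true(all(out > 0 & out < 1))
  }
  expect_error(model_forward(m, array(0.5, c(10, 10, 1))), "divisible")
})

test_that("ablation toggles change the parameter count as expected", {
  full <- build_model(model_config(), seed = 1)
  no_ag <- build_model(model_config(use_ag = FALSE), seed = 1)
  plain <- build_model(model_config(use_cbam = FALSE, use_ag = FALSE),
                       seed = 1)
  expect_gt(n_parameters(full), n_parameters(no_ag))
  expect_gt(n_parameters(no_ag), n_parameters(plain))
  # plain variant equals a vanilla U-Net parameter count computed
  # independently from the filter ladder
  convp <- function(k, cin, cout) k * k * cin * cout + cout
  f <- 32 * 2^(0:3)
  expected <- 0
  cin <- 1
  for (fi in f) { expected <- expected + convp(3, cin, fi) + convp(3, fi, fi); cin <- fi }
  expected <- expected + convp(3, 256, 512) + convp(3, 512, 512)
  up_in <- 512
  for (fi in rev(f)) {
    expected <- expected + (2 * 2 * up_in * fi + fi)        # transposed conv
    expected <- expected + convp(3, 2 * fi, fi) + convp(3, fi, fi)
    up_in <- fi
  }
  expected <- expected + convp(1, 32, 1)
  expect_equal(n_parameters(plain), expected)
})

test_that("backpropagation matches central finite differences", {
  cfg <- model_config(base_filters = 2L, depth = 2L, reduction_ratio = 2L)
  m <- build_model(cfg, seed = 3)
  set.seed(1)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  p <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 2, 1))
  lossfn <- function(model) bce_loss(model_forward(model, x)$out, p)
  fw <- model_forward(m, x, tape = TRUE)
  q <- fw$out
  dz <- bce_grad(q, p) * q * (1 - q)
  g <- masegnet:::model_backward(m, fw$tape, dz)
  leaves_p <- masegnet:::param_leaves(m$params)
  leaves_g <- masegnet:::param_leaves(g)
  expect_identical(names(leaves_p), names(leaves_g))
  poke <- function(model, path, j, delta) {
    mod <- function(l, path, j, delta) {
      if (!length(path)) { l[j] <- l[j] + delta; return(l) }
      key <- path[1]
      if (grepl("^[0-9]+$", key)) key <- as.integer(key)
      l[[key]] <- mod(l[[key]], path[-1], j, delta)
      l
    }
    model$params <- mod(model$params, path, j, delta)
    model
  }
  set.seed(42)
  h <- 1e-7
  checked <- 0
  for (trial in 1:15) {
    li <- sample(length(leaves_p), 1)
    j <- sample(length(leaves_p[[li]]), 1)
    path <- strsplit(names(leaves_p)[li], ".", fixed = TRUE)[[1]]
    num <- (lossfn(poke(m, path, j, h)) - lossfn(poke(m, path, j, -h))) / (2 * h)
    ana <- leaves_g[[li]][j]
    expect_equal(ana, num, tolerance = 1e-3)
    checked <- checked + 1
  }
  expect_equal(checked, 15)
})

test_that("one optimisation step on a patch strictly decreases the loss", {
  m <- build_model(model_config(base_filters = 4L, depth = 2L,
                                reduction_ratio = 2L), seed = 9)
  set.seed(2)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  y <- array(0, c(16, 16, 1, 1)); y[6:8, 6:8, 1, 1] <- 1
  fw <- model_forward(m, x, tape = TRUE)
  l0 <- bce_loss(fw$out, y)
  dz <- bce_grad(fw$out, y) * fw$out * (1 - fw$out)
  g <- masegnet:::model_backward(m, fw$tape, dz)
  m$params <- masegnet:::param_map(function(p, gr) p - 0.05 * gr, m$params, g)
  l1 <- bce_loss(model_forward(m, x)$out, y)
  expect_lt(l1, l0)
})
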