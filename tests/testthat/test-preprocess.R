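make_rgb <- function(h, w, value = 120) array(value, c(h, w, 3L))

test_that("border crop finds the tight content bounding box", {
  img <- make_rgb(100, 200, 0)
  img[, 50:149, ] <- 120
  out <- crop_border(img, threshold = 10)
  expect_equal(dim(out)[1:2], c(100L, 100L))
  full <- make_rgb(50, 60, 80)
  expect_equal(dim(crop_border(full, 10))[1:2], c(50L, 60L))
  expect_error(crop_border(make_rgb(20, 20, 0), 10), "no content")
})

test_that("bilinear resize is exact on identity, constants, and 2x block means", {
  set.seed(4)
  img <- matrix(runif(30 * 20, 0, 255), 30, 20)
  expect_equal(resize_image(img, c(30, 20)), img, tolerance = 1e-12)
  cst <- matrix(77, 16, 16)
  expect_true(all(abs(resize_image(cst, c(5, 9)) - 77) < 1e-12))
  cb <- matrix(runif(16, 0, 255), 4, 4)
  got <- resize_image(cb, c(2, 2))
  ref <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    ref[i, j] <- mean(cb[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(got, ref, tolerance = 1e-12)
  expect_error(resize_image(img, c(0, 5)), "positive")
})

test_that("nearest-neighbour resize keeps masks binary", {
  set.seed(1)
  mask <- matrix(rbinom(64 * 64, 1, 0.1), 64, 64)
  out <- resize_image(mask, c(40, 40), "nearest")
  expect_true(all(out %in% c(0, 1)))
})

test_that("green extraction is an exact channel slice", {
  g <- make_rgb(8, 8, 0); g[, , 2] <- 200
  expect_true(all(extract_green(g) == 200))
  r <- make_rgb(8, 8, 0); r[, , 1] <- 200
  expect_true(all(extract_green(r) == 0))
  set.seed(2)
  img <- array(runif(10 * 12 * 3, 0, 255), c(10, 12, 3))
  expect_identical(extract_green(img), img[, , 2])
  expect_error(extract_green(matrix(1, 4, 4)), "three-channel")
})

test_that("CLAHE preserves constants, range, and expands ramp contrast", {
  cst <- matrix(128, 64, 64)
  out <- apply_clahe(cst)
  expect_lt(diff(range(out)), 1e-9)
  set.seed(3)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  eq <- apply_clahe(img)
  expect_true(all(eq >= 0 & eq <= 255))
  ramp <- matrix(rep(seq(110, 140, length.out = 64), each = 64), 64, 64)
  expect_gt(sd(apply_clahe(ramp)), sd(ramp))
  expect_error(apply_clahe(img, clip_limit = 0), "positive")
})

test_that("gamma correction follows the power-law map", {
  expect_equal(apply_gamma(matrix(255, 2, 2), 0.7)[1, 1], 255)
  set.seed(5)
  img <- matrix(runif(16, 0, 255), 4, 4)
  expect_equal(apply_gamma(img, 1), img, tolerance = 1e-12)
  # (128/255)^0.9 * 255, frozen from an independent scalar evaluation
  expect_equal(apply_gamma(matrix(128, 1, 1), 0.9)[1, 1], 137.1333201,
               tolerance = 1e-6)
  # gamma < 1 brightens every pixel
  expect_true(all(apply_gamma(img, 0.9) >= img))
  expect_error(apply_gamma(img, 0), "positive")
})

test_that("non-local means preserves constants and suppresses noise", {
  cst <- matrix(90, 48, 48)
  expect_lt(max(abs(denoise_nlm(cst) - 90)), 1e-8)
  set.seed(6)
  noisy <- matrix(100 + rnorm(64 * 64, 0, 10), 64, 64)
  expect_lt(var(as.vector(denoise_nlm(noisy))), var(as.vector(noisy)))
  imp <- matrix(50, 33, 33); imp[17, 17] <- 250
  out <- denoise_nlm(imp)
  expect_lt(out[17, 17] - 50, 200)
  expect_error(denoise_nlm(cst, template_window = 6), "odd")
  expect_error(denoise_nlm(cst, template_window = 7, search_window = 5),
               "exceed")
})

test_that("patch extraction produces the expected grids", {
  img <- matrix(runif(512 * 512), 512, 512)
  ps <- extract_patches(img, 64)
  expect_length(ps$patches, 64)
  one <- extract_patches(img[1:64, 1:64], 64)
  expect_length(one$patches, 1)
  expect_identical(one$patches[[1]], img[1:64, 1:64])
  odd <- extract_patches(matrix(0, 130, 70), 64)
  expect_length(odd$patches, 2)
  expect_equal(unname(odd$coords), rbind(c(0L, 0L), c(1L, 0L)))
  expect_error(extract_patches(matrix(0, 32, 32), 64), "exceeds")
})

test_that("stitching inverts extraction and is order-independent", {
  set.seed(7)
  for (rep in 1:5) {
    p <- sample(c(4L, 8L, 16L), 1)
    h <- p * sample(1:4, 1); w <- p * sample(1:4, 1)
    img <- matrix(runif(h * w), h, w)
    ps <- extract_patches(img, p)
    expect_identical(stitch_patches(ps), img)
    ord <- sample(length(ps$patches))
    ps$patches <- ps$patches[ord]
    ps$coords <- ps$coords[ord, , drop = FALSE]
    expect_identical(stitch_patches(ps), img)
  }
  one <- extract_patches(matrix(as.numeric(1:16), 4, 4), 4)
  expect_identical(stitch_patches(one), matrix(as.numeric(1:16), 4, 4))
  broken <- extract_patches(matrix(0, 8, 8), 4)
  broken$patches <- broken$patches[-2]
  broken$coords <- broken$coords[-2, , drop = FALSE]
  expect_error(stitch_patches(broken), "missing patch coords")
})

test_that("augmentation ops are involutions / 4-cycles and track masks", {
  set.seed(8)
  m <- matrix(runif(36), 6, 6)
  expect_identical(hflip(hflip(m)), m)
  expect_identical(vflip(vflip(m)), m)
  expect_identical(rotate90(rotate90(rotate90(rotate90(m)))), m)
  # a single-pixel mask at (r, c) moves to (r, W - 1 - c) under hflip
  mask <- matrix(0, 5, 8); mask[2, 3] <- 1
  flipped <- hflip(mask)
  expect_equal(which(flipped == 1, arr.ind = TRUE)[1, ],
               c(row = 2, col = 8 - 3 + 1))
  # lesion pixel count is invariant under every op
  for (f in list(hflip, vflip, rotate90)) expect_equal(sum(f(mask)), sum(mask))
})

test_that("augmentation expands pairs exactly fourfold", {
  set.seed(9)
  imgs <- replicate(5, matrix(runif(16), 4, 4), simplify = FALSE)
  msks <- replicate(5, matrix(rbinom(16, 1, 0.3), 4, 4), simplify = FALSE)
  out <- augment_pairs(imgs, msks)
  expect_length(out$images, 20)
  expect_length(out$masks, 20)
  # each op applied identically to patch and mask
  i4 <- which(out$op == "hflip")[1]
  expect_identical(out$images[[i4]], hflip(imgs[[1]]))
  expect_identical(out$masks[[i4]], hflip(msks[[1]]))
  expect_error(augment_pairs(imgs, msks[1:3]), "misaligned")
})

test_that("the preprocessing chain composes its stages in order", {
  fx <- generate_fundus(synth_config(image_size = 128, seed = 13))
  out <- preprocess_fundus(fx$image, size = 128)
  expect_equal(attr(out, "stages"),
               c("crop", "resize", "green", "clahe", "gamma", "denoise"))
  manual <- crop_border(fx$image, 10)
  manual <- resize_image(manual, 128)
  manual <- extract_green(manual)
  manual <- apply_clahe(manual)
  manual <- apply_gamma(manual, 0.9)
  manual <- denoise_nlm(manual)
  attr(out, "stages") <- NULL
  expect_equal(out, manual, tolerance = 1e-12)
  expect_true(all(out >= 0 & out <= 255))
  # constant mid-gray input survives with the right shape
  cst <- preprocess_fundus(make_rgb(128, 128, 128), size = 64, crop = FALSE)
  expect_equal(dim(cst), c(64L, 64L))
})

test_that("paired preprocessing keeps masks binary and aligned", {
  fx <- generate_fundus(synth_config(image_size = 256, seed = 17))
  pr <- preprocess_pair(fx$image, fx$mask, size = 128)
  expect_equal(dim(pr$image), c(128L, 128L))
  expect_equal(dim(pr$mask), c(128L, 128L))
  expect_true(all(pr$mask %in% c(0, 1)))
  expect_gt(sum(pr$mask), 0)
})
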