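# Seeded synthetic fundus images with paired microaneurysm masks.  The
# generator reproduces the statistical structure the segmentation method
# targets: a circular field of view on a black backdrop, a reddish-orange
# textured background, dark curvilinear vessels as confusable distractors,
# and sparse, tiny, low-contrast circular lesions whose contrast drop is
# deepest in the green channel.  Vessels are deliberately absent from the
# mask: only lesions are foreground.

#' Synthetic fundus configuration
#'
#' Ranges are sampled uniformly per image.  Defaults give a 512 x 512 image
#' with 3-20 lesions of radius 1-4 px, matching the size and sparsity of
#' real microaneurysms at this working resolution, and a lesion pixel
#' fraction well below 1% (the class imbalance the method is built for).
#'
#' @param image_size square image side in pixels (at least 64).
#' @param n_lesions inclusive integer range of lesion counts.
#' @param lesion_radius lesion radius range in pixels.
#' @param lesion_contrast fractional intensity drop range of a lesion in
#'   the green channel (red/blue drop half as much).
#' @param n_vessels vessel count range.
#' @param vessel_width vessel stroke width range in pixels.
#' @param fov_radius_frac field-of-view radius as a fraction of half the
#'   image side.
#' @param noise_sigma additive Gaussian pixel noise, intensity units.
#' @param seed integer seed; the same seed gives bit-identical output.
#' @return a `masegnet_synth_config` list.
#' @export
synth_config <- function(image_size = 512L, n_lesions = c(3L, 20L),
                         lesion_radius = c(1, 4),
                         lesion_contrast = c(0.1, 0.4),
                         n_vessels = c(4L, 10L), vessel_width = c(2, 6),
                         fov_radius_frac = 0.95, noise_sigma = 3,
                         seed = 1L) {
  if (image_size < 64) stop("image_size must be at least 64 to host a patch")
  stopifnot(n_lesions[1L] >= 0, lesion_radius[1L] > 0,
            fov_radius_frac > 0, fov_radius_frac <= 1)
  structure(list(image_size = as.integer(image_size),
                 n_lesions = as.integer(n_lesions),
                 lesion_radius = lesion_radius,
                 lesion_contrast = lesion_contrast,
                 n_vessels = as.integer(n_vessels),
                 vessel_width = vessel_width,
                 fov_radius_frac = fov_radius_frac,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "masegnet_synth_config")
}

sample_range <- function(rng, n = 1L) {
  if (rng[1L] == rng[2L]) rep(rng[1L], n) else stats::runif(n, rng[1L], rng[2L])
}

sample_int_range <- function(rng) {
  if (rng[1L] == rng[2L]) rng[1L] else sample(seq(rng[1L], rng[2L]), 1L)
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

stamp_disks <- function(mask, centers, radius) {
  s <- nrow(mask)
  off <- disk_offsets(radius)
  rr <- rep(round(centers[, 1L]), each = nrow(off)) + off$dr
  cc <- rep(round(centers[, 2L]), each = nrow(off)) + off$dc
  keep <- rr >= 1 & rr <= s & cc >= 1 & cc <= s
  mask[cbind(rr[keep], cc[keep])] <- TRUE
  mask
}

#' Generate one synthetic fundus image with its lesion mask
#'
#' @param config a [synth_config()].
#' @return list with `image` (`S x S x 3` array, integers in `[0, 255]`)
#'   and `mask` (`S x S` binary 0/1 matrix marking exactly the lesion
#'   disks).
#' @export
generate_fundus <- function(config = synth_config()) {
  stopifnot(inherits(config, "masegnet_synth_config"))
  set.seed(config$seed)
  s <- config$image_size
  ctr <- (s + 1) / 2
  fov_r <- config$fov_radius_frac * s / 2
  rows <- matrix(seq_len(s), s, s)
  cols <- matrix(seq_len(s), s, s, byrow = TRUE)
  dist2 <- (rows - ctr)^2 + (cols - ctr)^2
  fov <- dist2 <= fov_r^2
  # background: radial brightness falloff plus low-frequency texture
  coarse <- matrix(stats::rnorm(16 * 16, 0, 12), 16, 16)
  texture <- resize_image(coarse, s, "bilinear")
  falloff <- 1 - 0.35 * pmin(dist2 / fov_r^2, 1)
  base <- c(r = 175, g = 95, b = 35)
  tex_gain <- c(r = 1, g = 0.8, b = 0.5)
  img <- array(0, c(s, s, 3L))
  for (ch in 1:3) img[, , ch] <- base[ch] * falloff + tex_gain[ch] * texture
  # vessels: random quadratic Bezier strokes, darker than background
  nv <- sample_int_range(config$n_vessels)
  vessel <- matrix(FALSE, s, s)
  if (nv > 0) {
    for (v in seq_len(nv)) {
      th <- stats::runif(2, 0, 2 * pi)
      p0 <- c(ctr + 0.9 * fov_r * sin(th[1L]), ctr + 0.9 * fov_r * cos(th[1L]))
      p2 <- c(ctr + 0.9 * fov_r * sin(th[2L]), ctr + 0.9 * fov_r * cos(th[2L]))
      mid <- (p0 + p2) / 2
      perp <- c(-(p2 - p0)[2L], (p2 - p0)[1L])
      nrm <- sqrt(sum(perp^2)) + 1e-9
      p1 <- mid + perp / nrm * stats::runif(1, -0.5, 0.5) * fov_r
      tt <- seq(0, 1, length.out = 4L * s)
      bez <- cbind((1 - tt)^2 * p0[1L] + 2 * (1 - tt) * tt * p1[1L] + tt^2 * p2[1L],
                   (1 - tt)^2 * p0[2L] + 2 * (1 - tt) * tt * p1[2L] + tt^2 * p2[2L])
      w <- sample_range(config$vessel_width)
      vessel <- stamp_disks(vessel, bez, w / 2)
    }
  }
  vfac <- vessel & fov
  vgain <- c(r = 0.55, g = 0.45, b = 0.6)
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[vfac] <- pl[vfac] * vgain[ch]
    img[, , ch] <- pl
  }
  # lesions: non-overlapping dark disks fully inside the field of view,
  # contrast drop deepest in the green channel
  nl <- sample_int_range(config$n_lesions)
  mask <- matrix(FALSE, s, s)
  if (nl > 0) {
    radii <- sample_range(config$lesion_radius, nl)
    contr <- sample_range(config$lesion_contrast, nl)
    sep <- 2 * max(config$lesion_radius) + 3
    centers <- matrix(0, 0, 2L)
    tries <- 0L
    while (nrow(centers) < nl && tries < 20000L) {
      tries <- tries + 1L
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * (fov_r - max(radii) - 2)
      cand <- c(ctr + rad * sin(ang), ctr + rad * cos(ang))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2L, cand)^2))) >= sep)
        centers <- rbind(centers, cand)
    }
    if (nrow(centers) < nl)
      stop("could not place ", nl, " non-overlapping lesions; ",
           "reduce n_lesions or lesion_radius")
    for (i in seq_len(nl)) {
      off <- disk_offsets(radii[i])
      rr <- round(centers[i, 1L]) + off$dr
      cc <- round(centers[i, 2L]) + off$dc
      idx <- cbind(rr, cc)
      mask[idx] <- TRUE
      drop_g <- 1 - contr[i]
      drop_rb <- 1 - 0.5 * contr[i]
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[idx] <- pl[idx] * if (ch == 2L) drop_g else drop_rb
        img[, , ch] <- pl
      }
    }
  }
  # pixel noise, field-of-view cut, 8-bit quantisation
  img <- img + array(stats::rnorm(s * s * 3, 0, config$noise_sigma),
                     c(s, s, 3L))
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[!fov] <- 0
    img[, , ch] <- pl
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, mask = mask * 1)
}

#' Generate a dataset of synthetic fundus/mask pairs
#'
#' Writes `image_NNN.png` / `mask_NNN.png` pairs plus a JSON manifest
#' recording the train/test split and per-image seeds.  Each image uses
#' seed `config$seed + i`, so the whole dataset is reproducible from one
#' integer.
#'
#' @param n_train,n_test number of training and test images.
#' @param config a [synth_config()]; per-image seeds are derived from
#'   `config$seed`.
#' @param out_dir output directory (created if needed).
#' @param overwrite allow replacing an existing manifest.
#' @return the manifest as a data.frame (invisibly also written to
#'   `manifest.json`).
#' @export
generate_dataset <- function(n_train, n_test, config = synth_config(),
                             out_dir, overwrite = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists at ", manifest_path,
         "; use overwrite = TRUE to replace it")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_train + n_test
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- config
    ci$seed <- config$seed + i
    fx <- generate_fundus(ci)
    id <- sprintf("%03d", i)
    img_file <- paste0("image_", id, ".png")
    mask_file <- paste0("mask_", id, ".png")
    write_png(fx$image, file.path(out_dir, img_file))
    write_png(fx$mask * 255, file.path(out_dir, mask_file))
    rows[[i]] <- data.frame(id = id, image = img_file, mask = mask_file,
                            split = if (i <= n_train) "train" else "test",
                            seed = ci$seed)
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, manifest_path, pretty = TRUE)
  invisible(manifest)
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @param split `"train"`, `"test"`, or `"all"`.
#' @return list of `list(image, mask)` pairs on the 0-255 / 0-1 scales.
#' @export
load_dataset <- function(dir, split = c("all", "train", "test")) {
  split <- match.arg(split)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (split != "all") manifest <- manifest[manifest$split == split, ]
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_image(file.path(dir, manifest$image[i]))
    msk <- read_image(file.path(dir, manifest$mask[i]))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
    list(image = img, mask = (msk > 127) * 1, id = manifest$id[i],
         split = manifest$split[i])
  })
}
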