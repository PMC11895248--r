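# Non-overlapping patch grids with lossless stitch-back, and deterministic
# geometric augmentation applied identically to image and mask tiles.

#' Extract a non-overlapping patch grid
#'
#' Tiles an image into `patch_size` x `patch_size` patches in row-major
#' order.  When the patch size does not divide an image dimension the
#' residual margin is dropped, so a 512 x 512 image with 64-pixel patches
#' yields the full 8 x 8 grid of 64 patches.
#'
#' @param image numeric matrix (`H x W`) or array (`H x W x C`).
#' @param patch_size tile side in pixels; must not exceed either image
#'   dimension.
#' @return a `masegnet_patches` list: `patches` (row-major list of tiles),
#'   `coords` (0-based `(row, col)` grid indices), `source_size`,
#'   `patch_size`.
#' @export
extract_patches <- function(image, patch_size = 64L) {
  d <- dim(image)
  if (is.null(d)) stop("image must be a matrix or array")
  patch_size <- as.integer(patch_size)
  if (patch_size > min(d[1:2]))
    stop("patch_size ", patch_size, " exceeds image extent ",
         d[1L], "x", d[2L])
  nr <- d[1L] %/% patch_size
  nc <- d[2L] %/% patch_size
  patches <- vector("list", nr * nc)
  coords <- matrix(0L, nr * nc, 2L, dimnames = list(NULL, c("row", "col")))
  i <- 0L
  for (r in seq_len(nr) - 1L) for (cc in seq_len(nc) - 1L) {
    i <- i + 1L
    rows <- r * patch_size + seq_len(patch_size)
    cols <- cc * patch_size + seq_len(patch_size)
    patches[[i]] <- if (length(d) == 2L) image[rows, cols]
                    else image[rows, cols, , drop = FALSE]
    coords[i, ] <- c(r, cc)
  }
  structure(list(patches = patches, coords = coords,
                 source_size = d[1:2], patch_size = patch_size),
            class = "masegnet_patches")
}

#' Stitch a patch grid back into an image
#'
#' Inverse of [extract_patches()] on the tiled extent: placement is driven
#' by the stored grid coordinates, so tile order is irrelevant.  Exact
#' round-trip when the patch size divides both image dimensions.
#'
#' @param patchset a `masegnet_patches` object with a complete grid.
#' @return matrix (or array) covering the tiled extent of the source.
#' @export
stitch_patches <- function(patchset) {
  stopifnot(inherits(patchset, "masegnet_patches"))
  p <- patchset$patch_size
  nr <- patchset$source_size[1L] %/% p
  nc <- patchset$source_size[2L] %/% p
  want <- paste(rep(seq_len(nr) - 1L, each = nc),
                rep(seq_len(nc) - 1L, times = nr))
  have <- paste(patchset$coords[, 1L], patchset$coords[, 2L])
  missing <- setdiff(want, have)
  if (length(missing))
    stop("missing patch coords: ", paste0("(", missing, ")", collapse = ", "))
  first <- patchset$patches[[1L]]
  nch <- if (length(dim(first)) >= 3L) dim(first)[3L] else 1L
  out <- if (nch == 1L) matrix(0, nr * p, nc * p)
         else array(0, c(nr * p, nc * p, nch))
  for (i in seq_along(patchset$patches)) {
    r <- patchset$coords[i, 1L]; cc <- patchset$coords[i, 2L]
    rows <- r * p + seq_len(p); cols <- cc * p + seq_len(p)
    if (nch == 1L) out[rows, cols] <- patchset$patches[[i]]
    else out[rows, cols, ] <- patchset$patches[[i]]
  }
  out
}

apply_to_planes <- function(x, f) {
  if (is.matrix(x)) return(f(x))
  d <- dim(x)
  out <- x
  for (ch in seq_len(d[3L])) out[, , ch] <- f(x[, , ch])
  out
}

#' Geometric augmentation primitives
#'
#' `hflip` mirrors columns, `vflip` mirrors rows, `rotate90` rotates a
#' quarter turn counter-clockwise.  All are involutions or 4-cycles, applied
#' identically to images and masks.
#'
#' @param x matrix or `H x W x C` array.
#' @return transformed copy of `x`.
#' @export
hflip <- function(x) apply_to_planes(x, function(m) m[, rev(seq_len(ncol(m)))])

#' @rdname hflip
#' @export
vflip <- function(x) apply_to_planes(x, function(m) m[rev(seq_len(nrow(m))), ])

#' @rdname hflip
#' @export
rotate90 <- function(x) {
  if (is.matrix(x)) return(t(x)[rev(seq_len(ncol(x))), ])
  d <- dim(x)
  out <- array(0, c(d[2L], d[1L], d[3L]))
  for (ch in seq_len(d[3L])) out[, , ch] <- t(x[, , ch])[rev(seq_len(d[2L])), ]
  out
}

aug_op <- function(name) {
  switch(name, rotate90 = rotate90, hflip = hflip, vflip = vflip,
         stop("unknown augmentation op: ", name))
}

#' Deterministic augmentation expansion
#'
#' Expands aligned image/mask tile lists by applying every requested
#' geometric op to each pair; with the default three ops and
#' `keep_original = TRUE`, n input pairs become 4n output pairs (the exact
#' x4 expansion that turns 4096 training patches into 16384).
#'
#' @param images,masks aligned lists of tiles (matrices), or
#'   `masegnet_patches` objects.
#' @param ops character vector from `"rotate90"`, `"hflip"`, `"vflip"`.
#' @param keep_original include the untransformed pair.
#' @return list with `images`, `masks` (lists of tiles) and `op` (the op
#'   that produced each pair).
#' @export
augment_pairs <- function(images, masks,
                          ops = c("rotate90", "hflip", "vflip"),
                          keep_original = TRUE) {
  if (inherits(images, "masegnet_patches")) images <- images$patches
  if (inherits(masks, "masegnet_patches")) masks <- masks$patches
  if (length(images) != length(masks))
    stop("images and masks are misaligned: ", length(images), " vs ",
         length(masks))
  fns <- lapply(ops, aug_op)
  out_i <- list(); out_m <- list(); out_op <- character(0)
  for (j in seq_along(images)) {
    if (keep_original) {
      out_i <- c(out_i, images[j]); out_m <- c(out_m, masks[j])
      out_op <- c(out_op, "original")
    }
    for (k in seq_along(fns)) {
      out_i <- c(out_i, list(fns[[k]](images[[j]])))
      out_m <- c(out_m, list(fns[[k]](masks[[j]])))
      out_op <- c(out_op, ops[k])
    }
  }
  list(images = out_i, masks = out_m, op = out_op)
}
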