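# Fundus preprocessing chain: border crop -> resize -> green channel ->
# CLAHE -> gamma correction -> fast non-local-means denoising.  All stages
# keep intensities on the [0, r_max] scale (255 for 8-bit input).

#' Read an image file
#'
#' Reads PNG, TIFF or JPEG into an `H x W x C` array on the 0-255 scale
#' (grayscale files give an `H x W` matrix).
#'
#' @param path image file.
#' @return numeric array in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                jpg = , jpeg = {
                  x <- EBImage::imageData(EBImage::readImage(path))
                  if (length(dim(x)) == 3L) aperm(x, c(2L, 1L, 3L)) else t(x)
                },
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) img <- img[, , 1:3]
  img * 255
}

#' Write an image or mask as PNG
#'
#' @param image numeric matrix/array on the 0-255 scale (or 0/1 binary
#'   mask, written as 0/255).
#' @param path destination file.
#' @export
write_png <- function(image, path) {
  mx <- max(image)
  if (mx <= 1) image <- image * 255
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Crop away the dark border
#'
#' Returns the tight bounding box of pixels whose maximum channel
#' intensity exceeds `threshold`, removing the black backdrop around the
#' circular field of view.
#'
#' @param image `H x W x 3` array (or matrix) in `[0, r_max]`.
#' @param threshold intensity below which a pixel counts as background.
#' @return cropped image; attribute `"bbox"` holds `(row0, row1, col0,
#'   col1)` so the same crop can be applied to a paired mask.
#' @export
crop_border <- function(image, threshold = 10) {
  if (threshold < 0) stop("threshold must be non-negative")
  mx <- if (length(dim(image)) == 3L) {
    pmax(image[, , 1L], image[, , 2L], image[, , 3L])
  } else image
  above <- mx > threshold
  keep_r <- which(rowSums(above) > 0)
  keep_c <- which(colSums(above) > 0)
  if (!length(keep_r) || !length(keep_c))
    stop("image is entirely below the border threshold; no content found")
  r <- range(keep_r); cc <- range(keep_c)
  out <- if (length(dim(image)) == 3L)
    image[r[1L]:r[2L], cc[1L]:cc[2L], , drop = FALSE]
  else image[r[1L]:r[2L], cc[1L]:cc[2L], drop = FALSE]
  attr(out, "bbox") <- c(r, cc)
  out
}

crop_to_bbox <- function(image, bbox) {
  if (length(dim(image)) == 3L)
    image[bbox[1L]:bbox[2L], bbox[3L]:bbox[4L], , drop = FALSE]
  else image[bbox[1L]:bbox[2L], bbox[3L]:bbox[4L], drop = FALSE]
}

nearest_index <- function(src, dst) {
  pmax(1L, pmin(src, as.integer(floor((seq_len(dst) - 0.5) * src / dst) + 1L)))
}

#' Resize an image
#'
#' Bilinear interpolation (half-pixel-centre convention) for intensity
#' images; nearest-neighbour for masks, which must stay binary.
#'
#' @param image matrix or `H x W x C` array.
#' @param size target `(H, W)` (a single value is used for both).
#' @param method `"bilinear"` or `"nearest"`.
#' @return resized image with exactly the requested dimensions.
#' @export
resize_image <- function(image, size, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (length(size) == 1L) size <- c(size, size)
  if (any(size < 1)) stop("target size must be positive")
  d <- dim(image)
  plane <- function(m) {
    if (method == "bilinear") {
      S <- bilinear_matrix(d[1L], d[2L], size[1L], size[2L])
      matrix(as.vector(S %*% as.vector(m)), size[1L], size[2L])
    } else {
      m[nearest_index(d[1L], size[1L]), nearest_index(d[2L], size[2L]),
        drop = FALSE]
    }
  }
  if (length(d) == 2L) return(plane(image))
  out <- array(0, c(size, d[3L]))
  for (ch in seq_len(d[3L])) out[, , ch] <- plane(image[, , ch])
  out
}

#' Extract the green channel
#'
#' The green channel carries the highest contrast between microaneurysms
#' and the retinal background, so all later stages operate on it alone.
#'
#' @param image `H x W x 3` array ordered (r, g, b).
#' @return `H x W` matrix, bit-identical to channel 2 of the input.
#' @export
extract_green <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("expected a three-channel (r, g, b) image, got dims ",
         paste(d, collapse = "x"))
  image[, , 2L]
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Per-tile histogram equalisation on a non-overlapping grid (8 x 8 by
#' default) with clip-limited contrast amplification and bilinear blending
#' between tiles.
#'
#' @param gray `H x W` matrix in `[0, r_max]`.
#' @param grid tile grid as `(nx, ny)`.
#' @param clip_limit contrast clip limit (> 0).
#' @param r_max intensity ceiling.
#' @return equalised matrix in `[0, r_max]`.
#' @export
apply_clahe <- function(gray, grid = c(8L, 8L), clip_limit = 2,
                        r_max = 255) {
  if (clip_limit <= 0) stop("clip_limit must be positive")
  out <- EBImage::imageData(EBImage::clahe(EBImage::Image(t(gray) / r_max),
                                           nx = grid[1L], ny = grid[2L],
                                           limit = clip_limit))
  pmin(pmax(t(out) * r_max, 0), r_max)
}

#' Gamma correction
#'
#' Pointwise power-law remapping `((R / r_max)^gamma) * r_max`; the default
#' `gamma = 0.9` brightens mid-tones slightly, countering over-exposure
#' after equalisation.
#'
#' @param gray `H x W` matrix in `[0, r_max]`.
#' @param gamma exponent (> 0).
#' @param r_max intensity ceiling.
#' @return corrected matrix in `[0, r_max]`.
#' @export
apply_gamma <- function(gray, gamma = 0.9, r_max = 255) {
  if (gamma <= 0) stop("gamma must be positive")
  ((gray / r_max)^gamma) * r_max
}

#' Fast non-local-means denoising
#'
#' Averages pixels weighted by the similarity of their template
#' neighbourhoods across a search window; patch distances are box-filtered
#' with integral images so the cost is independent of the template size.
#'
#' @param gray `H x W` matrix in `[0, r_max]`.
#' @param strength filtering strength `h` (intensity units).
#' @param template_window odd template (patch) side.
#' @param search_window odd search-window side, larger than the template.
#' @return denoised matrix, same scale as the input.
#' @export
denoise_nlm <- function(gray, strength = 10, template_window = 7L,
                        search_window = 21L) {
  if (template_window %% 2L == 0L || search_window %% 2L == 0L)
    stop("window sizes must be odd")
  if (search_window <= template_window)
    stop("search_window must exceed template_window")
  d <- dim(gray)
  out <- nlm_denoise_cpp(as.vector(gray), d[1L], d[2L], strength,
                         as.integer(template_window),
                         as.integer(search_window))
  matrix(out, d[1L], d[2L])
}

#' Full preprocessing chain
#'
#' Applies, in order: border crop, resize to `size`, green-channel
#' extraction, CLAHE, gamma correction, and non-local-means denoising.
#' The executed stage order is recorded in the `"stages"` attribute.
#'
#' @param image `H x W x 3` fundus image in `[0, 255]`.
#' @param size working resolution (default 512).
#' @param crop_threshold border threshold for [crop_border()].
#' @param clip_limit CLAHE clip limit.
#' @param gamma gamma-correction exponent.
#' @param nlm_strength,nlm_template,nlm_search denoiser parameters.
#' @param crop apply the border crop (disable for synthetic images already
#'   tight to the field of view).
#' @return `size x size` grayscale matrix in `[0, 255]`.
#' @export
preprocess_fundus <- function(image, size = 512L, crop_threshold = 10,
                              clip_limit = 2, gamma = 0.9,
                              nlm_strength = 10, nlm_template = 7L,
                              nlm_search = 21L, crop = TRUE) {
  stages <- character(0)
  if (crop) {
    image <- crop_border(image, crop_threshold)
    stages <- c(stages, "crop")
  }
  image <- resize_image(image, size, "bilinear")
  gray <- extract_green(image)
  gray <- apply_clahe(gray, clip_limit = clip_limit)
  gray <- apply_gamma(gray, gamma = gamma)
  gray <- denoise_nlm(gray, strength = nlm_strength,
                      template_window = nlm_template,
                      search_window = nlm_search)
  attr(gray, "stages") <- c(stages, "resize", "green", "clahe", "gamma",
                            "denoise")
  gray
}

#' Preprocess an image/mask pair
#'
#' Runs [preprocess_fundus()] on the image and applies the identical crop
#' box and a nearest-neighbour resize to the mask, re-thresholding at 0.5
#' so the mask stays binary.
#'
#' @param image `H x W x 3` fundus image.
#' @param mask `H x W` binary lesion mask (0/1 or 0/255).
#' @inheritParams preprocess_fundus
#' @param ... further arguments passed to [preprocess_fundus()].
#' @return list with `image` (`size x size` gray matrix) and `mask`
#'   (`size x size` binary 0/1 matrix).
#' @export
preprocess_pair <- function(image, mask, size = 512L, crop_threshold = 10,
                            crop = TRUE, ...) {
  if (max(mask) > 1) mask <- mask / max(mask)
  if (crop) {
    cropped <- crop_border(image, crop_threshold)
    mask <- crop_to_bbox(mask, attr(cropped, "bbox"))
    image <- cropped
  }
  gray <- preprocess_fundus(image, size = size, crop = FALSE, ...)
  mask <- resize_image(mask, size, "nearest")
  list(image = gray, mask = (mask > 0.5) * 1)
}
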