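#' Grayscale image container
#'
#' A minimal container for a 2-D single-channel microscopy image: an intensity
#' matrix plus the declared bit depth \code{b}. Pixel values are stored as
#' doubles in \code{[0, 2^b - 1]}; quantization back to integers happens only
#' when the image is written to file.
#'
#' @param pixels numeric matrix (height x width) of intensities.
#' @param bit_depth integer, bits per pixel (e.g. 12 for a camera with 12-bit
#'   dynamic range stored in 16-bit files).
#' @return An object of class \code{gray_image} with fields \code{pixels} and
#'   \code{bit_depth}.
#' @examples
#' img <- gray_image(matrix(0:99, 10, 10), bit_depth = 8)
#' range(img$pixels)
#' @export
gray_image <- function(pixels, bit_depth = 12L) {
  if (is.list(pixels) && inherits(pixels, "gray_image")) return(pixels)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  bit_depth <- as.integer(bit_depth)
  if (length(bit_depth) != 1L || is.na(bit_depth) || bit_depth < 1L || bit_depth > 16L)
    stop("bit_depth must be a single integer in 1..16")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (any(!is.finite(pixels)))
    stop("image contains non-finite pixel values")
  mx <- 2^bit_depth - 1
  if (min(pixels) < 0 || max(pixels) > mx)
    stop(sprintf("pixel values outside [0, %d] for bit depth %d", mx, bit_depth))
  structure(list(pixels = pixels, bit_depth = bit_depth), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d-bit, range [%.1f, %.1f]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

# Coerce matrix-or-gray_image input; internal.
as_gray_image <- function(x, bit_depth = 12L) {
  if (inherits(x, "gray_image")) x else gray_image(x, bit_depth)
}

# Intensity ceiling 2^b - 1.
imax <- function(img) 2^img$bit_depth - 1

#' Read a grayscale image from TIFF or PNG
#'
#' The declared bit depth is taken from the file's sample format (8 or 16)
#' unless overridden; 12-bit cameras conventionally store data in 16-bit
#' containers, so pass \code{bit_depth = 12} for such files.
#'
#' @param path file path (.tif/.tiff or .png).
#' @param bit_depth optional override of the declared bit depth.
#' @return A [gray_image].
#' @export
read_image <- function(path, bit_depth = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE, all = FALSE)
    meta <- tiff::readTIFF(path, payload = FALSE)
    file_bits <- if (!is.null(meta$bits.per.sample)) meta$bits.per.sample else 16L
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    file_bits <- 16L
    if (max(raw) <= 1) {
      # png package returns [0,1]; recover integer codes at 16-bit precision
      px <- round(raw * 65535)
      if (all(px %% 257 == 0)) { px <- px / 257; file_bits <- 8L }
    } else px <- raw
  } else stop("unsupported image format: .", ext)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] > 1L)
      stop("RGB/multi-channel input: extract a single channel before reading")
    px <- px[, , 1L]
  }
  gray_image(px, if (is.null(bit_depth)) file_bits else bit_depth)
}

#' Write a grayscale image to TIFF or PNG
#'
#' Values are rounded to integers on write. Images with bit depth <= 8 are
#' written as 8-bit, otherwise as 16-bit samples.
#'
#' @param img a [gray_image] (or matrix, taken as 12-bit).
#' @param path output path (.tif/.tiff or .png).
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as_gray_image(img)
  bits <- if (img$bit_depth <= 8L) 8L else 16L
  scaled <- round(img$pixels) / (2^bits - 1)
  scaled[scaled > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = bits)
  } else if (ext == "png") {
    png::writePNG(scaled, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Read / write label masks
#'
#' Label masks are non-negative integer rasters (0 = background, k >= 1 =
#' object k), stored as 16-bit TIFF or PNG. Binary masks written by
#' [write_mask()] use 0/255 8-bit PNG.
#'
#' @param path file path.
#' @return \code{read_labels}: an integer matrix of labels.
#' @export
read_labels <- function(path) {
  img <- read_image(path, bit_depth = 16L)
  lab <- round(img$pixels)
  storage.mode(lab) <- "integer"
  lab
}

#' @rdname read_labels
#' @param labels integer matrix of labels.
#' @export
write_labels <- function(labels, path) {
  labels <- as.matrix(labels)
  if (max(labels) > 65535) stop("more than 65535 labels cannot be stored")
  write_image(gray_image(labels, 16L), path)
}

#' @rdname read_labels
#' @param mask logical or 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  m <- matrix(as.numeric(mask != 0) * 255, nrow(mask), ncol(mask))
  write_image(gray_image(m, 8L), path)
}

#' @rdname read_labels
#' @export
read_mask <- function(path) {
  img <- read_image(path, bit_depth = 8L)
  img$pixels > (imax(img) / 2)
}

# Reflect-pad a matrix by `pad` samples on every side (symmetric half-sample
# reflection, supports pad larger than the image via index mirroring).
pad_reflect <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  ridx <- mirror_index(seq_len(nr + 2 * pad) - pad, nr)
  cidx <- mirror_index(seq_len(nc + 2 * pad) - pad, nc)
  m[ridx, cidx, drop = FALSE]
}

mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j[j < 0] <- j[j < 0] + 2L * n
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Convolve with arbitrary kernel under reflect padding (EBImage FFT filter
# on the padded image, then crop).
convolve_reflect <- function(m, kern) {
  pad <- max(dim(kern) %/% 2)
  if (pad == 0) return(m * kern[1])
  mp <- pad_reflect(m, pad)
  out <- EBImage::imageData(EBImage::filter2(EBImage::Image(mp), kern, boundary = "circular"))
  out[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m)), drop = FALSE]
}

# 8-connected labelling of a logical mask.
label_components <- function(mask) {
  .cc_label8(matrix(as.integer(mask != 0), nrow(mask)))
}

# Drop connected components smaller than min_area pixels (8-connectivity).
remove_small_objects <- function(mask, min_area) {
  if (min_area <= 0) return(mask)
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  keep <- which(tabulate(lab[lab > 0L], nbins = max(lab)) >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Flat disc structuring element: pixel included iff its center lies within
# `radius` of the origin.
disc_brush <- function(radius) {
  r <- ceiling(radius)
  d <- 2L * r + 1L
  idx <- seq(-r, r)
  mask <- outer(idx^2, idx^2, "+") <= radius^2
  matrix(as.numeric(mask), d, d)
}

box_brush <- function(ksize) matrix(1, ksize, ksize)

# EBImage grayscale morphology clamps intensities to [0,1]; flat morphology
# commutes with monotone affine maps, so normalize, apply, map back.
morph_gray <- function(px, kern, op) {
  rng <- range(px)
  if (diff(rng) == 0) return(px)
  p01 <- (px - rng[1]) / diff(rng)
  out <- EBImage::imageData(op(EBImage::Image(p01), kern))
  out * diff(rng) + rng[1]
}
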