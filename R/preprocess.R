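#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' The image is divided into a grid of tiles, each tile's histogram is
#' equalized with its peak clipped (so homogeneous regions are not
#' over-amplified), and neighbouring tile mappings are blended by bilinear
#' interpolation. Histograms use 256 bins spanning the occupied intensity
#' range of the image, so low-contrast images are still spread over the full
#' representable range, as adaptive equalization conventionally does.
#'
#' @param img a [gray_image] (or matrix, taken as 12-bit).
#' @param tiles tile grid size (scalar: tiles x tiles), default 8.
#' @param clip_fraction histogram clip limit as a fraction of the tile pixel
#'   count, default 0.01.
#' @return A [gray_image] of the same size and bit depth.
#' @export
clahe_enhance <- function(img, tiles = 8L, clip_fraction = 0.01) {
  img <- as_gray_image(img)
  tiles <- as.integer(tiles)
  if (tiles < 1L) stop("tiles must be >= 1")
  if (nrow(img$pixels) < tiles || ncol(img$pixels) < tiles)
    stop(sprintf("image (%d x %d) smaller than one %d x %d tile grid cell per side",
                 nrow(img$pixels), ncol(img$pixels), tiles, tiles))
  rng <- range(img$pixels)
  if (diff(rng) == 0) return(img)  # constant image: clipping leaves it unchanged
  bins <- 256L
  x <- (img$pixels - rng[1]) / diff(rng)
  out <- EBImage::clahe(EBImage::Image(x), nx = tiles, ny = tiles,
                        bins = bins, limit = clip_fraction * bins,
                        keep.range = FALSE)
  out <- EBImage::imageData(out)
  out <- pmin(pmax(out, 0), 1) * imax(img)
  gray_image(matrix(out, nrow(img$pixels)), img$bit_depth)
}

#' Morphological opening by reconstruction
#'
#' The marker image is the erosion of the input by a flat disc-shaped
#' structuring element; it is then grown back under the input by iterated
#' geodesic dilation until stability. Unlike a plain opening this preserves
#' the topology and exact shape of bright plateaus while flattening specks
#' narrower than the disc.
#'
#' @param img a [gray_image] (or matrix, taken as 12-bit).
#' @param radius disc radius in pixels, default 5.
#' @return A [gray_image], pointwise less than or equal to the input.
#' @export
opening_by_reconstruction <- function(img, radius = 5) {
  img <- as_gray_image(img)
  if (radius < 1) stop("radius must be >= 1")
  kern <- disc_brush(radius)
  pad <- (nrow(kern) - 1L) %/% 2L
  mp <- pad_reflect(img$pixels, pad)
  marker <- morph_gray(mp, kern, EBImage::erode)
  marker <- marker[(pad + 1):(pad + nrow(img$pixels)),
                   (pad + 1):(pad + ncol(img$pixels)), drop = FALSE]
  rec <- .cc_reconstruct(pmin(marker, img$pixels), img$pixels)
  gray_image(rec, img$bit_depth)
}

#' Saturation contrast stretch
#'
#' Clips the lowest and highest \code{tail_fraction} intensity quantiles and
#' linearly stretches the remaining range to \code{[0, 2^b - 1]}.
#'
#' @param img a [gray_image] (or matrix, taken as 12-bit).
#' @param tail_fraction fraction saturated at each tail, default 0.01.
#' @return A [gray_image] spanning the full representable range (unless the
#'   input is constant, which is returned unchanged with a warning).
#' @export
saturate_rescale <- function(img, tail_fraction = 0.01) {
  img <- as_gray_image(img)
  if (tail_fraction < 0 || tail_fraction >= 0.5)
    stop("tail_fraction must be in [0, 0.5)")
  q <- stats::quantile(img$pixels, c(tail_fraction, 1 - tail_fraction),
                       names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    warning("constant (or degenerate) image: no stretch applied")
    return(img)
  }
  x <- (pmin(pmax(img$pixels, q[1]), q[2]) - q[1]) / (q[2] - q[1]) * imax(img)
  gray_image(x, img$bit_depth)
}

#' Pre-processing cascade
#'
#' The three-stage enhancement applied before segmentation: CLAHE (local
#' contrast), opening by morphological reconstruction (suppresses spurious
#' bright specks and evens out varying signal), and a saturation stretch
#' (clips 1% tails and restores the full dynamic range).
#'
#' @param img a [gray_image] (or matrix, taken as 12-bit).
#' @param tiles,clip_fraction CLAHE parameters, see [clahe_enhance()].
#' @param radius disc radius for [opening_by_reconstruction()].
#' @param tail_fraction tail fraction for [saturate_rescale()].
#' @return A [gray_image].
#' @examples
#' img <- gray_image(matrix(runif(64 * 64, 100, 900), 64, 64), 12)
#' out <- preprocess_cascade(img)
#' @export
preprocess_cascade <- function(img, tiles = 8L, clip_fraction = 0.01,
                               radius = 5, tail_fraction = 0.01) {
  img <- as_gray_image(img)
  out <- clahe_enhance(img, tiles = tiles, clip_fraction = clip_fraction)
  out <- opening_by_reconstruction(out, radius = radius)
  if (diff(range(out$pixels)) == 0) return(out)  # constant stays constant, silently
  saturate_rescale(out, tail_fraction = tail_fraction)
}
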