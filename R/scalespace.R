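#' Gaussian scale-space representation
#'
#' Builds the family \eqn{L(\cdot,\cdot;t^2) = g(\cdot,\cdot;t^2) * f} of
#' progressively smoothed versions of an image, where \eqn{g} is a rotationally
#' symmetric Gaussian of standard deviation \eqn{t}. At \eqn{t = 0} the
#' representation is the image itself (no convolution). Kernels are truncated
#' at \eqn{4t} and renormalized to unit mass; borders use reflect padding.
#'
#' @param img a [gray_image] (or matrix, taken as 12-bit).
#' @param scales numeric vector of scales \eqn{t}, sorted ascending, first
#'   element 0. Default \code{0:6}, the cytoplasm profile.
#' @return An object of class \code{scale_space_stack}: list with
#'   \code{images} (list of matrices) and \code{scales}.
#' @examples
#' st <- gaussian_scale_space(matrix(runif(100, 0, 4095), 10, 10), 0:3)
#' length(st$images)
#' @export
gaussian_scale_space <- function(img, scales = 0:6) {
  img <- as_gray_image(img)
  scales <- as.numeric(scales)
  if (length(scales) < 2L) stop("need at least two scales")
  if (any(scales < 0)) stop("scales must be non-negative")
  if (is.unsorted(scales, strictly = TRUE)) stop("scales must be strictly increasing")
  if (scales[1] != 0) stop("first scale must be 0 (the image itself)")
  images <- lapply(scales, function(t) {
    if (t == 0) return(img$pixels)
    convolve_reflect(img$pixels, gaussian_kernel(t))
  })
  structure(list(images = images, scales = scales, bit_depth = img$bit_depth),
            class = "scale_space_stack")
}

#' @export
print.scale_space_stack <- function(x, ...) {
  cat(sprintf("<scale_space_stack> %d levels, t = [%s], %d x %d\n",
              length(x$scales), paste(x$scales, collapse = ", "),
              nrow(x$images[[1]]), ncol(x$images[[1]])))
  invisible(x)
}

# Truncated (4 sigma) unit-mass Gaussian kernel.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  idx <- seq(-r, r)
  k <- exp(-outer(idx^2, idx^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Coefficient of variation across a scale-space stack
#'
#' Per pixel, the dispersion of intensities across the stack levels divided
#' by their mean plus an offset \eqn{\epsilon} that guards against division
#' by zero at dark pixels. The image is high at background and outline pixels
#' (where smoothing changes intensity fast) and low inside cytoplasm.
#'
#' @param stack a \code{scale_space_stack} from [gaussian_scale_space()].
#' @param epsilon denominator offset, default 1.
#' @param variant \code{"std"} uses the standard deviation across levels (a
#'   true coefficient of variation); \code{"var"} uses the variance. Both use
#'   the population convention (divide by the number of levels).
#' @return An object of class \code{cov_image}: list with \code{values}
#'   (non-negative matrix), \code{epsilon}, \code{variant}.
#' @export
coefficient_of_variation <- function(stack, epsilon = 1, variant = c("std", "var")) {
  if (!inherits(stack, "scale_space_stack")) stop("stack must be a scale_space_stack")
  variant <- match.arg(variant)
  k <- length(stack$images)
  mu <- Reduce(`+`, stack$images) / k
  ss <- Reduce(`+`, lapply(stack$images, function(m) (m - mu)^2)) / k
  disp <- if (variant == "std") sqrt(ss) else ss
  vals <- disp / (mu + epsilon)
  structure(list(values = vals, epsilon = epsilon, variant = variant),
            class = "cov_image")
}

#' @export
print.cov_image <- function(x, ...) {
  cat(sprintf("<cov_image> %d x %d, variant %s, epsilon %g, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$variant, x$epsilon,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Coefficient-of-variation image enhancement
#'
#' Adds the inverted, min-max normalized coefficient-of-variation image to
#' the original: \eqn{f_{enh} = f + (2^b - 1 - f_{COV})} with \eqn{f_{COV}}
#' normalized to \eqn{[0, 2^b - 1]}. Cytoplasm pixels (low COV) receive the
#' full additive boost and end up clamped high, background and outline pixels
#' (high COV) receive little. The sum is linearly rescaled back to the
#' representable range.
#'
#' @param img a [gray_image] (or matrix, taken as 12-bit).
#' @param cov a \code{cov_image} from [coefficient_of_variation()].
#' @return A [gray_image] in \eqn{[0, 2^b - 1]}.
#' @export
cov_enhance <- function(img, cov) {
  img <- as_gray_image(img)
  if (!inherits(cov, "cov_image")) stop("cov must be a cov_image")
  if (!all(dim(cov$values) == dim(img$pixels))) stop("image / COV shape mismatch")
  mx <- imax(img)
  rng <- range(cov$values)
  if (diff(rng) == 0) {
    warning("constant COV image: treating normalized COV as zero")
    cov_norm <- matrix(0, nrow(cov$values), ncol(cov$values))
  } else {
    cov_norm <- (cov$values - rng[1]) / diff(rng) * mx
  }
  fenh <- img$pixels + (mx - cov_norm)
  rng2 <- range(fenh)
  if (diff(rng2) == 0) return(gray_image(matrix(mx, nrow(fenh), ncol(fenh)), img$bit_depth))
  gray_image((fenh - rng2[1]) / diff(rng2) * mx, img$bit_depth)
}

#' Otsu threshold segmentation
#'
#' Thresholds a grayscale image at the level maximizing the between-class
#' intensity variance of its 256-bin histogram. Foreground (above-threshold)
#' pixels correspond to cytoplasm or nuclei after COV enhancement.
#'
#' Degenerate histograms are disambiguated deterministically: when several
#' local maxima of the between-class variance lie within 12% of the global
#' maximum (which happens when a wide background competes with a small bright
#' object class), the highest threshold among them is chosen — the reading
#' consistent with the enhancement's polarity, where objects are clamped
#' high and everything else must fall below the cut.
#'
#' @param img a [gray_image] (or matrix, taken as 12-bit).
#' @return Logical matrix, \code{TRUE} = foreground, with the chosen
#'   threshold (intensity units) attached as attribute \code{"threshold"}.
#'   A constant image yields an all-background mask with a warning.
#' @export
otsu_threshold <- function(img) {
  img <- as_gray_image(img)
  if (diff(range(img$pixels)) == 0) {
    warning("constant image: returning all-background mask")
    return(matrix(FALSE, nrow(img$pixels), ncol(img$pixels)))
  }
  mx <- imax(img)
  nb <- 256L
  v <- pmin(floor(img$pixels / mx * nb), nb - 1)
  h <- tabulate(v + 1L, nbins = nb) / length(v)
  lev <- (seq_len(nb) - 0.5) / nb
  cw <- cumsum(h)
  cm <- cumsum(h * lev)
  mu_tot <- cm[nb]
  k <- seq_len(nb - 1L)
  w0 <- cw[k]; w1 <- 1 - w0
  bc <- ifelse(w0 > 0 & w1 > 0, (mu_tot * w0 - cm[k])^2 / (w0 * w1), 0)
  # strict local maxima of the between-class variance, with flat plateaus
  # collapsed to one candidate each (a plateau is a maximum only when both
  # its neighbours are strictly lower); candidate = right edge of the run
  r <- rle(bc)
  ends <- cumsum(r$lengths)
  nruns <- length(r$values)
  left <- c(-Inf, r$values[-nruns])
  right <- c(r$values[-1], -Inf)
  peak_runs <- which(r$values > left & r$values > right &
                     r$values >= (1 - 0.12) * max(bc))
  split <- max(ends[peak_runs])
  th <- split / nb * mx
  out <- img$pixels > th
  attr(out, "threshold") <- th
  out
}

#' Segmentation profile
#'
#' Bundles the scale list and minimum object area used by
#' [initial_segmentation()] for a given channel. The built-in profiles follow
#' the two image regimes the method was developed on: \code{"cytoplasm"}
#' (large cells, scales 0..6, minimum area 600), \code{"nuclei-large"}
#' (nuclei of the same magnification, scales 0..6 halved is not needed;
#' scales 0..6 with minimum area 600), and \code{"nuclei-small"} (lower
#' magnification nuclei of roughly 25 px diameter cells: scales 0, 0.5, ...,
#' 3 and minimum area 100).
#'
#' @param role one of \code{"cytoplasm"}, \code{"nuclei-large"},
#'   \code{"nuclei-small"}, or \code{"custom"}.
#' @param scales,min_object_area overrides for role \code{"custom"} (also
#'   accepted for the named roles).
#' @return A list of class \code{segmentation_profile}.
#' @export
segmentation_profile <- function(role = c("cytoplasm", "nuclei-large",
                                          "nuclei-small", "custom"),
                                 scales = NULL, min_object_area = NULL) {
  role <- match.arg(role)
  defaults <- switch(role,
    "cytoplasm"    = list(scales = 0:6, min_object_area = 600),
    "nuclei-large" = list(scales = 0:6, min_object_area = 600),
    "nuclei-small" = list(scales = seq(0, 3, by = 0.5), min_object_area = 100),
    "custom"       = list(scales = 0:6, min_object_area = 0))
  if (is.null(scales)) scales <- defaults$scales
  if (is.null(min_object_area)) min_object_area <- defaults$min_object_area
  if (min_object_area < 0) stop("min_object_area must be >= 0")
  structure(list(role = role, scales = as.numeric(scales),
                 min_object_area = min_object_area),
            class = "segmentation_profile")
}

#' Initial cytoplasm / nuclei segmentation
#'
#' The multi-scale pipeline producing the initial foreground/background mask:
#' Gaussian scale space, coefficient of variation, COV enhancement, Otsu
#' thresholding, and removal of connected components below the profile's
#' minimum object area (8-connectivity).
#'
#' @param img a preprocessed [gray_image] (or matrix, taken as 12-bit).
#' @param profile a [segmentation_profile()].
#' @param epsilon,variant passed to [coefficient_of_variation()].
#' @return Logical foreground mask.
#' @examples
#' m <- matrix(200, 64, 64); m[20:40, 20:40] <- 2500
#' mask <- initial_segmentation(gray_image(m, 12), segmentation_profile("custom"))
#' sum(mask) > 0
#' @export
initial_segmentation <- function(img, profile = segmentation_profile("cytoplasm"),
                                 epsilon = 1, variant = "std") {
  img <- as_gray_image(img)
  stack <- gaussian_scale_space(img, profile$scales)
  cov <- coefficient_of_variation(stack, epsilon = epsilon, variant = variant)
  enh <- cov_enhance(img, cov)
  mask <- otsu_threshold(enh)
  remove_small_objects(mask, profile$min_object_area)
}
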