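#' Default feature-bank configuration
#'
#' Parameter grids for the 11 filter families of the generic pixel-feature
#' bank. With the defaults the bank has exactly 290 named features:
#' Gaussian low-pass 24, integrated intensity 4, Laplacian of Gaussian 24,
#' difference of Gaussian 5, morphological top-hat 24, bottom-hat 24, local
#' binary pattern + contrast 2, variance 24, order statistics 9, Haralick 78
#' (13 statistics x 6 window sizes), Gabor 72 (6 sizes x 3 frequencies x 4
#' orientations).
#'
#' @return Named list of per-family parameter grids; pass (possibly edited)
#'   to [build_feature_specs()]. Setting a family to \code{NULL} disables it.
#' @export
default_feature_config <- function() {
  list(
    gauss   = list(sigma = seq(3, 49, by = 2)),
    int     = list(ksize = seq(3, 9, by = 2)),
    log     = list(sigma = seq(3, 49, by = 2)),
    dog     = list(sigma = seq(3, 13, by = 2)),     # 5 consecutive pairs
    tophat  = list(ksize = seq(3, 49, by = 2)),
    bothat  = list(ksize = seq(3, 49, by = 2)),
    lbp     = list(radius = 1),
    var     = list(ksize = seq(3, 49, by = 2)),
    ordstat = list(ksize = seq(3, 7, by = 2)),
    haralick = list(ksize = seq(5, 15, by = 2)),
    gabor   = list(ksize = seq(5, 15, by = 2),
                   freq = c(1, 2, 3) / 4,
                   theta = c(0, 1, 2, 3) * pi / 4)
  )
}

# Haralick statistic codes, in the column order of .cc_haralick.
HARALICK_CODES <- c("ASM", "CON", "COR", "SSV", "IDM", "SAV", "SVA",
                    "SEN", "ENT", "DVA", "DOE", "IMOC1", "IMOC2")

format_theta <- function(theta) {
  frac <- theta / pi
  if (frac == 0) "0" else paste0(format(frac, trim = TRUE), "pi")
}

#' Build the ordered feature specification list
#'
#' Expands a feature-bank configuration into a deterministic ordered list of
#' named feature specifications. Feature names follow the grammar
#' \code{FAMILY[_param...]_KxK} (e.g. \code{VAR_3x3}, \code{MIN_7x7},
#' \code{IMOC2_9x9}, \code{GABOR_f0.25_th0_5x5}), the canonical link between
#' the feature bank, serialized classifier models and this package's
#' documentation.
#'
#' @param config a configuration list as returned by
#'   [default_feature_config()].
#' @return List of \code{feature_spec} objects (name, family, params).
#' @examples
#' length(build_feature_specs())  # 290
#' @export
build_feature_specs <- function(config = default_feature_config()) {
  specs <- list()
  add <- function(name, family, params) {
    specs[[length(specs) + 1L]] <<- structure(
      list(name = name, family = family, params = params),
      class = "feature_spec")
  }
  chk_odd <- function(k) {
    if (any(k %% 2 == 0) || any(k < 3))
      stop("kernel sizes must be odd and >= 3")
    as.integer(k)
  }
  if (!is.null(config$gauss))
    for (s in config$gauss$sigma) add(sprintf("GAUSS_s%g", s), "gauss", list(sigma = s))
  if (!is.null(config$int))
    for (k in chk_odd(config$int$ksize)) add(sprintf("INT_%dx%d", k, k), "int", list(ksize = k))
  if (!is.null(config$log))
    for (s in config$log$sigma) add(sprintf("LOG_s%g", s), "log", list(sigma = s))
  if (!is.null(config$dog)) {
    s <- config$dog$sigma
    if (length(s) < 2) stop("dog needs at least two sigmas")
    for (i in seq_len(length(s) - 1L))
      add(sprintf("DOG_s%g_%g", s[i], s[i + 1L]), "dog",
          list(sigma1 = s[i], sigma2 = s[i + 1L]))
  }
  if (!is.null(config$tophat))
    for (k in chk_odd(config$tophat$ksize)) add(sprintf("TOPHAT_%dx%d", k, k), "tophat", list(ksize = k))
  if (!is.null(config$bothat))
    for (k in chk_odd(config$bothat$ksize)) add(sprintf("BOTHAT_%dx%d", k, k), "bothat", list(ksize = k))
  if (!is.null(config$lbp)) {
    add("LBP_r1", "lbp", list(radius = 1L))
    add("LBPC_r1", "lbpc", list(radius = 1L))
  }
  if (!is.null(config$var))
    for (k in chk_odd(config$var$ksize)) add(sprintf("VAR_%dx%d", k, k), "var", list(ksize = k))
  if (!is.null(config$ordstat))
    for (k in chk_odd(config$ordstat$ksize))
      for (stat in c("MIN", "MED", "MAX"))
        add(sprintf("%s_%dx%d", stat, k, k), "ordstat", list(ksize = k, stat = stat))
  if (!is.null(config$haralick))
    for (k in chk_odd(config$haralick$ksize))
      for (code in HARALICK_CODES)
        add(sprintf("%s_%dx%d", code, k, k), "haralick", list(ksize = k, stat = code))
  if (!is.null(config$gabor))
    for (k in chk_odd(config$gabor$ksize))
      for (f in config$gabor$freq)
        for (th in config$gabor$theta)
          add(sprintf("GABOR_f%g_th%s_%dx%d", f, format_theta(th), k, k),
              "gabor", list(ksize = k, freq = f, theta = th))
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate feature names in configuration")
  specs
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> %s (family %s)\n", x$name, x$family))
  invisible(x)
}

#' Parse a feature name back into its specification
#'
#' Inverts the feature naming grammar, so serialized models (which store only
#' feature names) can be applied to new images.
#'
#' @param name a feature name such as \code{"VAR_3x3"} or
#'   \code{"GABOR_f0.25_th0.75pi_5x5"}.
#' @return A \code{feature_spec}.
#' @export
parse_feature_name <- function(name) {
  spec <- function(family, params) structure(
    list(name = name, family = family, params = params), class = "feature_spec")
  if (grepl("^GAUSS_s", name))
    return(spec("gauss", list(sigma = as.numeric(sub("^GAUSS_s", "", name)))))
  if (grepl("^LOG_s", name))
    return(spec("log", list(sigma = as.numeric(sub("^LOG_s", "", name)))))
  if (grepl("^DOG_s", name)) {
    ss <- as.numeric(strsplit(sub("^DOG_s", "", name), "_")[[1]])
    return(spec("dog", list(sigma1 = ss[1], sigma2 = ss[2])))
  }
  if (grepl("^INT_", name))
    return(spec("int", list(ksize = ksize_of(name))))
  if (grepl("^TOPHAT_", name)) return(spec("tophat", list(ksize = ksize_of(name))))
  if (grepl("^BOTHAT_", name)) return(spec("bothat", list(ksize = ksize_of(name))))
  if (name == "LBP_r1") return(spec("lbp", list(radius = 1L)))
  if (name == "LBPC_r1") return(spec("lbpc", list(radius = 1L)))
  if (grepl("^VAR_", name)) return(spec("var", list(ksize = ksize_of(name))))
  if (grepl("^(MIN|MED|MAX)_", name))
    return(spec("ordstat", list(ksize = ksize_of(name), stat = sub("_.*", "", name))))
  if (sub("_.*", "", name) %in% HARALICK_CODES)
    return(spec("haralick", list(ksize = ksize_of(name), stat = sub("_.*", "", name))))
  if (grepl("^GABOR_f", name)) {
    body <- sub("^GABOR_f", "", name)
    parts <- strsplit(body, "_")[[1]]
    f <- as.numeric(parts[1])
    ths <- sub("^th", "", parts[2])
    th <- if (ths == "0") 0 else as.numeric(sub("pi$", "", ths)) * pi
    return(spec("gabor", list(ksize = ksize_of(name), freq = f, theta = th)))
  }
  stop("cannot parse feature name: ", name)
}

ksize_of <- function(name) {
  m <- regmatches(name, regexpr("[0-9]+x[0-9]+$", name))
  if (!length(m)) stop("no kernel size in feature name: ", name)
  as.integer(strsplit(m, "x")[[1]][1])
}

# --- kernels -----------------------------------------------------------------

log_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  idx <- seq(-r, r)
  r2 <- outer(idx^2, idx^2, "+")
  g <- exp(-r2 / (2 * sigma^2))
  k <- (r2 - 2 * sigma^2) / sigma^4 * g
  k - mean(k)   # force zero response to constants
}

gabor_kernel <- function(ksize, freq, theta) {
  r <- (ksize - 1L) / 2L
  idx <- seq(-r, r)
  X <- matrix(rep(idx, each = ksize), ksize, ksize)   # column offset
  Y <- matrix(rep(idx, times = ksize), ksize, ksize)  # row offset
  xr <- X * cos(theta) + Y * sin(theta)
  yr <- -X * sin(theta) + Y * cos(theta)
  sigma <- (ksize - 1) / 4
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  list(re = env * cos(2 * pi * freq * xr),
       im = env * sin(2 * pi * freq * xr))
}

quantize_levels <- function(px, nlevels = 32L) {
  rng <- range(px)
  if (diff(rng) == 0) {
    q <- matrix(0L, nrow(px), ncol(px))
  } else {
    q <- floor((px - rng[1]) / diff(rng) * nlevels)
    q[q >= nlevels] <- nlevels - 1L
    storage.mode(q) <- "integer"
  }
  q
}

# Morphological filtering with a box structuring element under reflect padding.
morph_box <- function(px, ksize, op) {
  pad <- ksize  # opening/closing need kernel-sized support on each side
  mp <- pad_reflect(px, pad)
  kern <- box_brush(ksize)
  out <- morph_gray(mp, kern, switch(op, open = EBImage::opening,
                                     close = EBImage::closing))
  out[(pad + 1):(pad + nrow(px)), (pad + 1):(pad + ncol(px)), drop = FALSE]
}

box_mean <- function(px, ksize) convolve_reflect(px, box_brush(ksize) / ksize^2)

# --- feature computation -----------------------------------------------------

#' Compute a single per-pixel feature raster
#'
#' Evaluates one feature specification over the whole image, returning a
#' response raster of the same shape. All neighborhood operations use reflect
#' padding, so responses are finite everywhere including at borders.
#'
#' @param img a [gray_image] (or matrix, taken as 12-bit).
#' @param spec a \code{feature_spec} (from [build_feature_specs()] or
#'   [parse_feature_name()]).
#' @return Numeric matrix of per-pixel responses.
#' @export
compute_feature <- function(img, spec) {
  img <- as_gray_image(img)
  px <- img$pixels
  k <- spec$params$ksize
  if (!is.null(k) && (k > nrow(px) || k > ncol(px)))
    stop(sprintf("kernel %d x %d larger than image", k, k))
  switch(spec$family,
    gauss  = convolve_reflect(px, gaussian_kernel(spec$params$sigma)),
    int    = convolve_reflect(px, box_brush(k)),
    log    = convolve_reflect(px, log_kernel(spec$params$sigma)),
    dog    = convolve_reflect(px, gaussian_kernel(spec$params$sigma1)) -
             convolve_reflect(px, gaussian_kernel(spec$params$sigma2)),
    tophat = px - morph_box(px, k, "open"),
    bothat = morph_box(px, k, "close") - px,
    lbp    = matrix(.cc_lbp(px, integer(0), integer(0))[, 1], nrow(px)),
    lbpc   = matrix(.cc_lbp(px, integer(0), integer(0))[, 2], nrow(px)),
    var    = pmax(box_mean(px^2, k) - box_mean(px, k)^2, 0),
    ordstat = {
      col <- match(spec$params$stat, c("MIN", "MED", "MAX"))
      matrix(.cc_order_stats(px, k, integer(0), integer(0))[, col], nrow(px))
    },
    haralick = {
      col <- match(spec$params$stat, HARALICK_CODES)
      q <- quantize_levels(px)
      matrix(.cc_haralick(q, k, 32L, integer(0), integer(0))[, col], nrow(px))
    },
    gabor = {
      kern <- gabor_kernel(k, spec$params$freq, spec$params$theta)
      sqrt(convolve_reflect(px, kern$re)^2 + convolve_reflect(px, kern$im)^2)
    },
    stop("unknown feature family: ", spec$family))
}

#' Compute the pixel-by-feature matrix
#'
#' Evaluates a list of feature specifications, optionally restricted to a
#' pixel subset (as done at training time, where only the sampled pixels
#' need features, and at test time, where only the model's selected features
#' are computed). Window-statistic families (order statistics, LBP, Haralick)
#' are evaluated directly at the requested pixels; convolution families are
#' evaluated as full rasters and indexed.
#'
#' @param img a [gray_image] (or matrix, taken as 12-bit).
#' @param specs list of \code{feature_spec}s (default: the full 290 bank).
#' @param pixels optional integer matrix with columns (row, col), 1-based; if
#'   omitted all pixels are used in column-major order.
#' @return An object of class \code{feature_matrix}: list with \code{values}
#'   (N x P), \code{feature_names}, \code{pixel_index} (N x 2, 1-based).
#' @examples
#' specs <- build_feature_specs()[c(1, 30)]
#' fm <- compute_feature_matrix(matrix(runif(400, 0, 4095), 20, 20), specs)
#' dim(fm$values)
#' @export
compute_feature_matrix <- function(img, specs = build_feature_specs(),
                                   pixels = NULL) {
  img <- as_gray_image(img)
  px <- img$pixels
  if (length(specs) == 0L) stop("specs must be non-empty")
  if (inherits(specs, "feature_spec")) specs <- list(specs)
  nr <- nrow(px); nc <- ncol(px)
  if (is.null(pixels)) {
    pixels <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  } else {
    pixels <- as.matrix(pixels)
    if (ncol(pixels) != 2L) stop("pixels must have two columns (row, col)")
    if (min(pixels) < 1L || max(pixels[, 1]) > nr || max(pixels[, 2]) > nc)
      stop("pixel index out of bounds")
  }
  n <- nrow(pixels)
  rows0 <- as.integer(pixels[, 1] - 1L)
  cols0 <- as.integer(pixels[, 2] - 1L)
  lin <- (pixels[, 2] - 1L) * nr + pixels[, 1]
  fams <- vapply(specs, `[[`, "", "family")
  names_ <- vapply(specs, `[[`, "", "name")
  vals <- matrix(NA_real_, n, length(specs))

  # grouped window-statistic families (share the expensive window pass)
  hara_cache <- list(); ord_cache <- list(); lbp_cache <- NULL; qimg <- NULL
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    if (sp$family == "haralick") {
      key <- as.character(sp$params$ksize)
      if (is.null(hara_cache[[key]])) {
        if (is.null(qimg)) qimg <- quantize_levels(px)
        hara_cache[[key]] <- .cc_haralick(qimg, sp$params$ksize, 32L, rows0, cols0)
      }
      vals[, j] <- hara_cache[[key]][, match(sp$params$stat, HARALICK_CODES)]
    } else if (sp$family == "ordstat") {
      key <- as.character(sp$params$ksize)
      if (is.null(ord_cache[[key]]))
        ord_cache[[key]] <- .cc_order_stats(px, sp$params$ksize, rows0, cols0)
      vals[, j] <- ord_cache[[key]][, match(sp$params$stat, c("MIN", "MED", "MAX"))]
    } else if (sp$family %in% c("lbp", "lbpc")) {
      if (is.null(lbp_cache)) lbp_cache <- .cc_lbp(px, rows0, cols0)
      vals[, j] <- lbp_cache[, if (sp$family == "lbp") 1L else 2L]
    } else {
      vals[, j] <- compute_feature(img, sp)[lin]
    }
  }
  if (any(!is.finite(vals))) stop("non-finite feature values computed")
  colnames(vals) <- names_
  structure(list(values = vals, feature_names = names_, pixel_index = pixels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d pixels x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
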