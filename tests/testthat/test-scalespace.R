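test_that("scale space has the requested levels and t = 0 is the identity", {
  set.seed(1)
  img <- gray_image(matrix(runif(33 * 33, 0, 4095), 33, 33), 12)
  st <- gaussian_scale_space(img, 0:6)
  expect_length(st$images, 7)
  expect_identical(st$images[[1]], img$pixels)

  const <- gray_image(matrix(250, 20, 20), 12)
  stc <- gaussian_scale_space(const, c(0, 1, 2))
  for (m in stc$images) expect_equal(m, const$pixels, tolerance = 1e-9)

  expect_error(gaussian_scale_space(img, c(0, -1, 2)), "non-negative|increasing")
  expect_error(gaussian_scale_space(img, c(1, 2)), "first scale")
})

test_that("impulse response matches the truncated Gaussian kernel", {
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  st <- gaussian_scale_space(gray_image(imp, 12), c(0, 2))
  # oracle: direct kernel evaluation, truncation-corrected by renormalization
  t <- 2; r <- ceiling(4 * t)
  idx <- seq(-r, r)
  k <- exp(-outer(idx^2, idx^2, "+") / (2 * t^2))
  expect_equal(st$images[[2]][17, 17], k[r + 1, r + 1] / sum(k), tolerance = 1e-10)
  # and approximates the closed form 1/(2 pi t^2)
  expect_equal(st$images[[2]][17, 17], 1 / (2 * pi * t^2), tolerance = 1e-4)
})

test_that("per-pixel max over the stack is non-increasing in t for an impulse", {
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  st <- gaussian_scale_space(gray_image(imp, 12), 0:6)
  mx <- vapply(st$images, max, 0)
  expect_true(all(diff(mx) <= 1e-12))
})

test_that("smoothing preserves mean intensity", {
  const <- gaussian_scale_space(gray_image(matrix(77, 16, 16), 12), c(0, 3))
  expect_equal(mean(const$images[[2]]), 77, tolerance = 1e-9)
  set.seed(5)
  img <- matrix(runif(64 * 64, 0, 4095), 64, 64)
  st <- gaussian_scale_space(gray_image(img, 12), c(0, 2))
  expect_equal(mean(st$images[[2]]), mean(img), tolerance = mean(img) * 0.005)
})

test_that("coefficient of variation matches hand values and the per-pixel oracle", {
  expect_identical(eval(formals(coefficient_of_variation)$epsilon), 1)

  # constant stack -> zero dispersion
  const <- gaussian_scale_space(gray_image(matrix(100, 8, 8), 12), c(0, 1, 2))
  expect_equal(coefficient_of_variation(const)$values,
               matrix(0, 8, 8), tolerance = 1e-9)

  # two-level stack {0, 2}: std = var = 1, mean + 1 = 2 -> 0.5 either way
  stack <- structure(list(images = list(matrix(0, 4, 4), matrix(2, 4, 4)),
                          scales = c(0, 1), bit_depth = 12L),
                     class = "scale_space_stack")
  for (v in c("std", "var"))
    expect_equal(coefficient_of_variation(stack, 1, v)$values,
                 matrix(0.5, 4, 4))

  set.seed(11)
  img <- gray_image(matrix(runif(12 * 12, 0, 4095), 12, 12), 12)
  st <- gaussian_scale_space(img, 0:3)
  for (v in c("std", "var"))
    expect_equal(coefficient_of_variation(st, 1, v)$values,
                 oracle_cov(st$images, 1, v), tolerance = 1e-12)
})

test_that("COV enhancement implements f + (2^b - 1 - cov_norm) with rescale", {
  set.seed(2)
  px <- matrix(runif(100, 0, 4095), 10, 10)
  img <- gray_image(px, 12)
  cv <- structure(list(values = matrix(runif(100, 0, 3), 10, 10),
                       epsilon = 1, variant = "std"), class = "cov_image")
  out <- cov_enhance(img, cv)$pixels
  rng <- range(cv$values)
  cov_norm <- (cv$values - rng[1]) / diff(rng) * 4095
  fenh <- px + (4095 - cov_norm)
  ref <- (fenh - min(fenh)) / diff(range(fenh)) * 4095
  expect_equal(out, ref, tolerance = 1e-9)
  # where cov_norm is maximal the additive term vanishes; where it is zero
  # the full 2^b - 1 is added (checked through the pre-rescale image)
  expect_equal(fenh[which.max(cv$values)], px[which.max(cv$values)])
  expect_equal(fenh[which.min(cv$values)], px[which.min(cv$values)] + 4095)

  cvc <- structure(list(values = matrix(1, 10, 10), epsilon = 1,
                        variant = "std"), class = "cov_image")
  expect_warning(cov_enhance(img, cvc), "constant")
})

test_that("Otsu threshold separates bimodal data and matches the exhaustive oracle", {
  px <- matrix(10, 20, 20)
  px[sample.int(400, 160)] <- 200
  m <- otsu_threshold(gray_image(px, 8))
  expect_equal(m, px == 200, ignore_attr = TRUE)
  th <- attr(m, "threshold")
  expect_true(th > 10 && th < 200)

  set.seed(8)
  px2 <- matrix(c(rnorm(600, 700, 90), rnorm(424, 3300, 180)), 32, 32)
  px2 <- pmin(pmax(px2, 0), 4095)
  img <- gray_image(px2, 12)
  th_oracle <- oracle_otsu(px2, 4095)
  m2 <- otsu_threshold(img)
  expect_equal(m2, px2 > th_oracle, ignore_attr = TRUE)

  expect_warning(mc <- otsu_threshold(gray_image(matrix(7, 5, 5), 12)), "constant")
  expect_false(any(mc))
})

test_that("initial segmentation finds disjoint blobs and is accurate on dipped interiors", {
  # dark noisy background: the COV cue distinguishes stable bright objects
  # from background whose noise is large relative to its mean
  set.seed(99)
  centers <- cbind(c(12, 12, 32, 52, 52), c(12, 52, 32, 12, 52))
  m <- matrix(40, 64, 64) + matrix(abs(rnorm(64 * 64, 0, 25)), 64, 64)
  for (i in 1:5) {
    d <- sqrt((row(m) - centers[i, 1])^2 + (col(m) - centers[i, 2])^2)
    m[d <= 7] <- 3000
  }
  img <- gray_image(pmin(m, 4095), 12)
  mask <- initial_segmentation(img, segmentation_profile("custom", min_object_area = 100))
  expect_identical(max(cellcontour:::label_components(mask)), 5L)

  # profiles carry the documented scale ladders and minimum areas
  expect_equal(segmentation_profile("nuclei-small")$scales, seq(0, 3, 0.5))
  expect_equal(segmentation_profile("cytoplasm")$min_object_area, 600)
  expect_equal(segmentation_profile("nuclei-small")$min_object_area, 100)

  s <- synth_generate(synth_config(seed = 41))
  pp <- preprocess_cascade(s$cytoplasm)
  mask <- initial_segmentation(pp, segmentation_profile("cytoplasm"))
  expect_gte(pixel_fmeasure(mask, s$cell_labels)$fmeasure, 0.95)
})
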