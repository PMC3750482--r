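test_that("default feature bank has 290 uniquely named features with the documented family counts", {
  specs <- build_feature_specs()
  expect_length(specs, 290)
  nm <- vapply(specs, `[[`, "", "name")
  expect_false(anyDuplicated(nm) > 0)
  fam <- table(vapply(specs, `[[`, "", "family"))
  expect_equal(fam[["gauss"]], 24)
  expect_equal(fam[["int"]], 4)
  expect_equal(fam[["log"]], 24)
  expect_equal(fam[["dog"]], 5)
  expect_equal(fam[["tophat"]], 24)
  expect_equal(fam[["bothat"]], 24)
  expect_equal(fam[["lbp"]] + fam[["lbpc"]], 2)
  expect_equal(fam[["var"]], 24)
  expect_equal(fam[["ordstat"]], 9)
  expect_equal(fam[["haralick"]], 78)
  expect_equal(fam[["gabor"]], 72)
})

test_that("family subsets, empty configs and invalid grids behave", {
  cfg <- list(haralick = list(ksize = seq(5, 15, 2)))
  expect_length(build_feature_specs(cfg), 78)
  expect_length(build_feature_specs(list()), 0)
  expect_error(build_feature_specs(list(var = list(ksize = c(3, 4)))), "odd")
})

test_that("feature names round-trip through the parser", {
  specs <- build_feature_specs()
  idx <- c(1, 25, 29, 50, 54, 78, 103, 107, 109, 130, 145, 200, 250, 290)
  for (sp in specs[idx]) {
    back <- parse_feature_name(sp$name)
    expect_identical(back$family, sp$family)
    expect_equal(back$params[order(names(back$params))],
                 sp$params[order(names(sp$params))],
                 tolerance = 1e-12)
  }
  expect_error(parse_feature_name("NOPE_3x3"), "cannot parse")
})

test_that("single-feature rasters match closed forms and sort oracles", {
  const <- gray_image(matrix(900, 16, 16), 12)
  expect_equal(compute_feature(const, parse_feature_name("VAR_3x3")),
               matrix(0, 16, 16), tolerance = 1e-6)
  expect_equal(compute_feature(const, parse_feature_name("ASM_5x5")),
               matrix(1, 16, 16))

  set.seed(4)
  px <- matrix(sample(0:4095, 49), 7, 7)
  img <- gray_image(px, 12)
  vals <- sort(as.vector(px))
  expect_equal(compute_feature(img, parse_feature_name("MIN_7x7"))[4, 4], vals[1])
  expect_equal(compute_feature(img, parse_feature_name("MED_7x7"))[4, 4], vals[25])
  expect_equal(compute_feature(img, parse_feature_name("MAX_7x7"))[4, 4], vals[49])

  expect_error(compute_feature(gray_image(matrix(0, 4, 4), 12),
                               parse_feature_name("MIN_7x7")), "larger than image")
})

test_that("Haralick features match a direct co-occurrence oracle", {
  set.seed(12)
  px <- matrix(sample(0:4095, 15 * 15, replace = TRUE), 15, 15)
  # include a checkerboard patch: strong structured co-occurrence
  px[4:10, 4:10] <- ifelse((row(matrix(0, 7, 7)) + col(matrix(0, 7, 7))) %% 2 == 0, 0, 4095)
  img <- gray_image(px, 12)
  q <- cellcontour:::quantize_levels(px)
  for (pix in list(c(7, 7), c(3, 12), c(13, 5))) {
    want <- oracle_haralick_pixel(q, pix[1], pix[2], 7, 32)
    for (stat in names(want)) {
      got <- compute_feature(img, parse_feature_name(sprintf("%s_7x7", stat)))
      expect_equal(got[pix[1], pix[2]], unname(want[stat]), tolerance = 1e-10,
                   label = stat)
    }
  }
})

test_that("all families are finite everywhere including borders", {
  set.seed(6)
  img <- gray_image(matrix(runif(28 * 28, 0, 4095), 28, 28), 12)
  specs <- build_feature_specs(list(
    gauss = list(sigma = c(3, 9)), int = list(ksize = 3),
    log = list(sigma = 3), dog = list(sigma = c(3, 5)),
    tophat = list(ksize = 5), bothat = list(ksize = 5),
    lbp = list(radius = 1), var = list(ksize = 5),
    ordstat = list(ksize = 3), haralick = list(ksize = 5),
    gabor = list(ksize = 5, freq = 0.25, theta = c(0, pi / 4))))
  for (sp in specs)
    expect_true(all(is.finite(compute_feature(img, sp))), label = sp$name)
})

test_that("features are translation covariant in the interior", {
  set.seed(7)
  base <- matrix(runif(40 * 40, 0, 4095), 40, 40)
  # circular shift by (2, 1): same value set, so range-based quantization
  # (Haralick) sees identical levels in both images
  shifted <- base[c(39:40, 1:38), c(40, 1:39)]
  for (nm in c("VAR_5x5", "ENT_5x5", "GABOR_f0.5_th0.25pi_5x5", "MIN_3x3")) {
    sp <- parse_feature_name(nm)
    a <- compute_feature(gray_image(base, 12), sp)
    b <- compute_feature(gray_image(shifted, 12), sp)
    # compare away from borders and the quantization edge effects
    expect_equal(b[13:30, 12:30], a[11:28, 11:29], tolerance = 1e-9, label = nm)
  }
})

test_that("Gabor magnitude is invariant to a pi rotation of orientation", {
  set.seed(10)
  # oriented bar fixture
  px <- matrix(100, 32, 32); px[, 15:17] <- 3500
  img <- gray_image(px, 12)
  for (th in c("0", "0.25pi")) {
    a <- compute_feature(img, parse_feature_name(sprintf("GABOR_f0.25_th%s_7x7", th)))
    k <- parse_feature_name(sprintf("GABOR_f0.25_th%s_7x7", th))$params
    sp2 <- structure(list(name = "tmp", family = "gabor",
                          params = list(ksize = 7, freq = 0.25,
                                        theta = k$theta + pi)),
                     class = "feature_spec")
    b <- compute_feature(img, sp2)
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("feature matrix rows agree with per-spec rasters at a pixel subset", {
  set.seed(13)
  img <- gray_image(matrix(runif(30 * 30, 0, 4095), 30, 30), 12)
  specs <- lapply(c("GAUSS_s3", "VAR_5x5", "MIN_3x3", "ENT_5x5", "LBP_r1",
                    "IMOC2_7x7", "GABOR_f0.25_th0_5x5"), parse_feature_name)
  pix <- cbind(sample(30, 10, TRUE), sample(30, 10, TRUE))
  fm <- compute_feature_matrix(img, specs, pix)
  expect_equal(dim(fm$values), c(10L, 7L))
  for (j in seq_along(specs)) {
    full <- compute_feature(img, specs[[j]])
    expect_equal(fm$values[, j], full[pix], tolerance = 1e-12,
                 label = specs[[j]]$name)
  }
  expect_error(compute_feature_matrix(img, specs, cbind(31, 1)), "out of bounds")
})
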